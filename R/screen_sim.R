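#' Screen simulation configuration
#'
#' Bundles the generative parameters of a synthetic splicing-reporter
#' screen. The defaults mirror the screen design the package targets:
#' four guides per gene (or gene pair), ~500 intergenic/non-targeting
#' controls, a high baseline percent intron retention (90), two technical
#' replicates, and 10 nt UMIs.
#'
#' @param n_genes Number of single-target genes.
#' @param guides_per_gene Guides per gene or gene-pair construct (default 4).
#' @param n_pair_constructs Number of combinatorial (gene-pair) constructs.
#' @param n_controls Number of intergenic/non-targeting control guides
#'   (default 500; must be > 0).
#' @param baseline_pir Baseline percent intron retention of the reporter in
#'   unperturbed cells, in `[0, 100]` (default 90).
#' @param effect_map Named numeric vector: gene -> true dPIR effect in
#'   percentage points; genes absent from the map are null. Effects of the
#'   two genes of a pair construct add. `baseline_pir + effect` is clamped
#'   to `[0, 100]`.
#' @param reads_per_guide_mean,reads_per_guide_dispersion Mean and
#'   negative-binomial size of the per-guide molecule count (defaults 500
#'   and 10).
#' @param duplication_rate Expected PCR copies per molecule (>= 1,
#'   default 1); per-molecule copy counts are geometric on `{1, 2, ...}`
#'   with this mean.
#' @param umi_len UMI length in nt (default 10).
#' @param n_replicates Number of technical replicates (default 2).
#' @param guide_len Guide sequence length in nt (default 20).
#' @param fpkm_meanlog,fpkm_sdlog Log-normal parameters of the simulated
#'   per-gene expression (FPKM); defaults `log(30)` and 1, which keeps
#'   essentially all genes above the 0.1 FPKM expression filter.
#' @param seed Integer seed.
#' @return An object of class `screen_sim_config` (a validated list).
#' @export
screen_sim_config <- function(n_genes,
                              guides_per_gene = 4L,
                              n_pair_constructs = 0L,
                              n_controls = 500L,
                              baseline_pir = 90,
                              effect_map = numeric(0),
                              reads_per_guide_mean = 500,
                              reads_per_guide_dispersion = 10,
                              duplication_rate = 1,
                              umi_len = 10L,
                              n_replicates = 2L,
                              guide_len = 20L,
                              fpkm_meanlog = log(30),
                              fpkm_sdlog = 1,
                              seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    guides_per_gene = as.integer(guides_per_gene),
    n_pair_constructs = as.integer(n_pair_constructs),
    n_controls = as.integer(n_controls),
    baseline_pir = baseline_pir,
    effect_map = effect_map,
    reads_per_guide_mean = reads_per_guide_mean,
    reads_per_guide_dispersion = reads_per_guide_dispersion,
    duplication_rate = duplication_rate,
    umi_len = as.integer(umi_len),
    n_replicates = as.integer(n_replicates),
    guide_len = as.integer(guide_len),
    fpkm_meanlog = fpkm_meanlog,
    fpkm_sdlog = fpkm_sdlog,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_genes >= 0, cfg$guides_per_gene >= 1, cfg$n_pair_constructs >= 0,
    cfg$n_controls > 0,
    cfg$baseline_pir >= 0, cfg$baseline_pir <= 100,
    cfg$reads_per_guide_mean > 0, cfg$reads_per_guide_dispersion > 0,
    cfg$duplication_rate >= 1,
    cfg$umi_len >= 1, cfg$n_replicates >= 1, cfg$guide_len >= 1
  )
  if (length(cfg$effect_map) &&
      (is.null(names(cfg$effect_map)) || any(names(cfg$effect_map) == ""))) {
    stop("effect_map must be a named numeric vector (gene -> dPIR)")
  }
  structure(cfg, class = "screen_sim_config")
}

.gene_names <- function(n) sprintf("gene%04d", seq_len(n))

#' Generate a synthetic guide library
#'
#' Builds the guide registry: `n_genes * guides_per_gene` single-gene
#' guides, `n_pair_constructs * guides_per_gene` pair-construct guides
#' (pairs drawn from the single-gene pool), and `n_controls`
#' intergenic/non-targeting controls. Guide sequences are unique random
#' DNA of length `guide_len`; duplicate draws are retried and generation
#' fails after a retry budget.
#'
#' @param config A [screen_sim_config()].
#' @return A data frame with columns `guide_id`, `sequence`, `category`
#'   (`single`, `pair`, `control`), `gene_a`, `gene_b` (NA except for
#'   pairs) and `target_id` (the gene, `geneA|geneB` for pairs, or NA for
#'   controls).
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  set.seed(config$seed)
  genes <- .gene_names(config$n_genes)
  if (config$n_pair_constructs > 0 && config$n_genes < 2) {
    stop("pair constructs require at least two genes")
  }

  rows <- list()
  gpg <- config$guides_per_gene
  for (g in genes) {
    rows[[length(rows) + 1L]] <- data.frame(
      category = "single", gene_a = g, gene_b = NA_character_,
      target_id = g, n = gpg, stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(config$n_pair_constructs)) {
    pr <- sort(sample(genes, 2L))
    rows[[length(rows) + 1L]] <- data.frame(
      category = "pair", gene_a = pr[1L], gene_b = pr[2L],
      target_id = paste(pr, collapse = "|"), n = gpg,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows)) {
    targets <- do.call(rbind, rows)
    targets <- targets[rep(seq_len(nrow(targets)), targets$n), , drop = FALSE]
    targets$n <- NULL
  } else {
    targets <- data.frame(category = character(0), gene_a = character(0),
                          gene_b = character(0), target_id = character(0),
                          stringsAsFactors = FALSE)
  }
  controls <- data.frame(
    category = rep("control", config$n_controls),
    gene_a = NA_character_, gene_b = NA_character_,
    target_id = NA_character_, stringsAsFactors = FALSE
  )
  lib <- rbind(targets, controls)
  lib <- data.frame(
    guide_id = sprintf("g%05d", seq_len(nrow(lib))),
    sequence = .unique_guides(nrow(lib), config$guide_len),
    lib, stringsAsFactors = FALSE
  )
  rownames(lib) <- NULL
  lib
}

.unique_guides <- function(n, len, max_retries = 50L) {
  seqs <- vapply(seq_len(n), function(i) random_dna(len), character(1))
  for (i in seq_len(max_retries)) {
    dup <- duplicated(seqs)
    if (!any(dup)) return(seqs)
    seqs[dup] <- vapply(seq_len(sum(dup)), function(i) random_dna(len),
                        character(1))
  }
  stop("could not generate unique guide sequences within retry budget")
}

# True per-guide IE probability: clamp(baseline + effect, 0, 100) / 100.
# Pair constructs add the effects of both genes; controls sit at baseline.
.true_ie_prob <- function(library, config) {
  eff <- numeric(nrow(library))
  em <- config$effect_map
  if (length(em)) {
    ea <- em[library$gene_a]
    eb <- em[library$gene_b]
    ea[is.na(ea)] <- 0
    eb[is.na(eb)] <- 0
    eff <- ea + eb
  }
  pmin(pmax(config$baseline_pir + eff, 0), 100) / 100
}

.encode_umi <- function(idx, umi_len) {
  # idx: 0-based integers < 4^umi_len, encoded base-4 as A/C/G/T
  bases <- c("A", "C", "G", "T")
  out <- matrix("", nrow = umi_len, ncol = length(idx))
  for (pos in seq_len(umi_len)) {
    out[pos, ] <- bases[idx %% 4 + 1]
    idx <- idx %/% 4
  }
  apply(out, 2L, paste, collapse = "")
}

#' Simulate molecule-level screen data for one replicate
#'
#' Draws, for every guide, a negative-binomial molecule count (mean
#' `reads_per_guide_mean`, size `reads_per_guide_dispersion`), assigns each
#' molecule an IE outcome with the guide's true retention probability
#' `clamp(baseline_pir + dPIR_true, 0, 100)/100` (controls at baseline),
#' and tags each molecule with a UMI drawn uniformly over `4^umi_len`.
#'
#' @param library Guide library from [generate_library()].
#' @param config A [screen_sim_config()].
#' @param replicate Replicate index; molecule draws are independent across
#'   replicates (each replicate is its own library prep).
#' @return A data frame of molecule records (`guide_id`, `umi`, `outcome`
#'   in `{IE, EE}`) with attribute `truth`: a per-guide data frame of
#'   `guide_id`, `p_true` and `n_molecules`.
#' @export
simulate_guide_molecules <- function(library, config, replicate = 1L) {
  stopifnot(inherits(config, "screen_sim_config"))
  set.seed(config$seed + 1000L * as.integer(replicate))
  p <- .true_ie_prob(library, config)
  n_mol <- rnbinom(nrow(library), mu = config$reads_per_guide_mean,
                   size = config$reads_per_guide_dispersion)
  total <- sum(n_mol)
  umi_space <- 4^config$umi_len
  umis <- .encode_umi(floor(stats::runif(total) * umi_space), config$umi_len)
  mol <- data.frame(
    guide_id = rep(library$guide_id, n_mol),
    umi = umis,
    outcome = ifelse(rbinom(total, 1L, rep(p, n_mol)) == 1L, "IE", "EE"),
    stringsAsFactors = FALSE
  )
  attr(mol, "truth") <- data.frame(
    guide_id = library$guide_id, p_true = p, n_molecules = n_mol,
    stringsAsFactors = FALSE
  )
  mol
}

#' Simulate deduplicated guide counts directly (count-level shortcut)
#'
#' Marginalizes the molecule-level generator: per guide and replicate,
#' `total ~ NegBin(mean, size)` and `ie ~ Binomial(total, p_true)`. This is
#' the exact distribution of the molecule-level counts before UMI
#' collisions and is the workhorse for large calibration simulations.
#'
#' @inheritParams simulate_guide_molecules
#' @return A data frame `guide_id`, `replicate`, `ie`, `ee`, `total` over
#'   all `config$n_replicates` replicates, with the per-guide `truth`
#'   attribute as in [simulate_guide_molecules()].
#' @export
simulate_guide_counts <- function(library, config) {
  stopifnot(inherits(config, "screen_sim_config"))
  p <- .true_ie_prob(library, config)
  out <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    set.seed(config$seed + 1000L * r)
    total <- rnbinom(nrow(library), mu = config$reads_per_guide_mean,
                     size = config$reads_per_guide_dispersion)
    ie <- rbinom(nrow(library), total, p)
    out[[r]] <- data.frame(
      guide_id = library$guide_id, replicate = r,
      ie = ie, ee = total - ie, total = total, stringsAsFactors = FALSE
    )
  }
  counts <- do.call(rbind, out)
  rownames(counts) <- NULL
  attr(counts, "truth") <- data.frame(
    guide_id = library$guide_id, p_true = p, stringsAsFactors = FALSE
  )
  counts
}

#' Simulate per-gene expression (FPKM) for a library
#'
#' Log-normal FPKM per gene; at the defaults essentially every gene
#' clears the 0.1 FPKM expression filter, so expression filtering only
#' bites when configured to.
#'
#' @param library Guide library.
#' @param config A [screen_sim_config()].
#' @return Data frame `gene`, `fpkm`, one row per distinct targeted gene.
#' @export
simulate_fpkm <- function(library, config) {
  genes <- sort(unique(stats::na.omit(c(library$gene_a, library$gene_b))))
  set.seed(config$seed + 77L)
  data.frame(gene = genes,
             fpkm = rlnorm(length(genes), config$fpkm_meanlog,
                           config$fpkm_sdlog),
             stringsAsFactors = FALSE)
}

#' Simulate a complete screen at the count level
#'
#' Convenience wrapper: library + deduplicated counts for all replicates +
#' per-gene FPKM + ground truth.
#'
#' @param config A [screen_sim_config()].
#' @return List with elements `library`, `counts`, `fpkm`, `truth`.
#' @export
simulate_screen <- function(config) {
  library <- generate_library(config)
  counts <- simulate_guide_counts(library, config)
  list(library = library, counts = counts,
       fpkm = simulate_fpkm(library, config),
       truth = attr(counts, "truth"))
}

#' Write / read a guide library as TSV
#' @param library Guide library data frame.
#' @param path File path.
#' @return `read_library` returns the library data frame.
#' @export
write_library <- function(library, path) {
  write.table(library, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  lib <- read.delim(path, stringsAsFactors = FALSE)
  for (col in c("guide_id", "sequence", "category", "gene_a", "gene_b",
                "target_id")) {
    if (col %in% names(lib)) lib[[col]] <- as.character(lib[[col]])
  }
  lib
}

#' Serialize simulation ground truth as TSV
#' @param truth Ground-truth data frame (attribute `truth` of a simulated
#'   object).
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a simulation configuration as YAML
#'
#' @param config A [screen_sim_config()] or [image_sim_config()].
#' @param path YAML path.
#' @return `read_screen_config` / `read_image_config` return the
#'   re-validated configuration object.
#' @export
write_sim_config <- function(config, path) {
  fields <- unclass(config)
  if (!is.null(fields$effect_map)) {
    # yaml serializes named atomic vectors as plain sequences; a list
    # round-trips as a map and keeps the gene names
    fields$effect_map <- as.list(fields$effect_map)
  }
  yaml::write_yaml(fields, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_screen_config <- function(path) {
  fields <- yaml::read_yaml(path)
  fields$effect_map <- unlist(fields$effect_map)
  if (is.null(fields$effect_map)) fields$effect_map <- numeric(0)
  do.call(screen_sim_config, fields)
}

#' @rdname write_sim_config
#' @export
read_image_config <- function(path) {
  do.call(image_sim_config, yaml::read_yaml(path))
}
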
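#' Configuration for the synthetic multi-assay dataset
#'
#' Defines the statistical conditions under which ground-truthed inputs are
#' generated: per gene and species a class is drawn (direct target, indirect
#' responder, or null), direct targets receive a planted seed site in their
#' UTR plus effects in all three assays, indirect responders respond in the
#' expression screen only, and null genes carry no effect anywhere.
#'
#' All randomness flows from `rng_seed` through a fixed splitting scheme:
#' each sub-generator seeds the RNG with `rng_seed + k` (truth k = 1, UTRs
#' k = 2, screen k = 3, pull-down k = 4, luciferase k = 5), so the same
#' configuration is byte-identical across runs and individual stages can be
#' regenerated independently.
#'
#' @param n_genes Number of genes.
#' @param species_list Species identifiers.
#' @param frac_direct,frac_indirect Expected fractions of direct targets and
#'   indirect responders per gene-species draw; their sum must be <= 1.
#' @param effect_log2fc Planted log2 expression change for screen responders
#'   (default 1, i.e. a 2-fold change, comfortably past the 1.3-fold cutoff).
#' @param noise_sd_ct Gaussian standard deviation of the per-replicate
#'   delta-Ct, in cycles (default 0.5, biological-replicate scale).
#' @param n_replicates Replicates per condition (>= 2; default 3).
#' @param luciferase_repression Planted relative reporter activity of direct
#'   targets under the miRNA duplex (default 0.5, the 40-60% repression
#'   band).
#' @param luciferase_cv Multiplicative (log-normal) noise coefficient of
#'   variation for luciferase readings (default 0.1).
#' @param pulldown_log2_enrichment Planted log2 pull-down enrichment of
#'   direct targets (default 2).
#' @param utr_length Length of synthetic UTRs (>= 30; default 300).
#' @param rng_seed Integer master seed.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 24L,
                              species_list = c("human", "mouse", "zebrafish"),
                              frac_direct = 0.4, frac_indirect = 0.3,
                              effect_log2fc = 1, noise_sd_ct = 0.5,
                              n_replicates = 3L, luciferase_repression = 0.5,
                              luciferase_cv = 0.1,
                              pulldown_log2_enrichment = 2,
                              utr_length = 300L, rng_seed = 1L) {
  n_genes <- as.integer(n_genes); n_replicates <- as.integer(n_replicates)
  utr_length <- as.integer(utr_length)
  if (n_genes < 1L) stop("n_genes must be positive", call. = FALSE)
  if (n_replicates < 2L) stop("n_replicates must be >= 2", call. = FALSE)
  if (frac_direct < 0 || frac_indirect < 0 || frac_direct + frac_indirect > 1) {
    stop("invalid class fractions: need frac_direct, frac_indirect >= 0 and their sum <= 1",
         call. = FALSE)
  }
  if (noise_sd_ct < 0) stop("noise_sd_ct must be >= 0", call. = FALSE)
  if (luciferase_repression <= 0 || luciferase_repression > 1) {
    stop("luciferase_repression must lie in (0, 1]", call. = FALSE)
  }
  if (utr_length < 30L) stop("utr_length must be >= 30", call. = FALSE)
  structure(
    list(n_genes = n_genes, species_list = as.character(species_list),
         frac_direct = frac_direct, frac_indirect = frac_indirect,
         effect_log2fc = effect_log2fc, noise_sd_ct = noise_sd_ct,
         n_replicates = n_replicates,
         luciferase_repression = luciferase_repression,
         luciferase_cv = luciferase_cv,
         pulldown_log2_enrichment = pulldown_log2_enrichment,
         utr_length = utr_length, rng_seed = as.integer(rng_seed)),
    class = "simulation_config"
  )
}

## Seed-splitting scheme: one documented offset per sub-generator.
sim_seed <- function(config, stage) {
  offsets <- c(truth = 1L, utrs = 2L, screen = 3L, pulldown = 4L,
               luciferase = 5L)
  config$rng_seed + offsets[[stage]]
}

#' Draw the ground-truth gene classification
#'
#' Each gene-species pair is independently assigned a class with
#' probabilities (`frac_direct`, `frac_indirect`, remainder null). Direct
#' targets carry planted effects in all three assays; indirect responders
#' only in the expression screen; null genes none.
#'
#' @param config A [simulation_config()].
#' @return Data frame of class `"truth_table"` with one row per gene and
#'   species: `gene`, `species`, `class`, `effect_screen_log2fc`,
#'   `effect_pulldown_log2`, `effect_luciferase` (relative activity), and
#'   planted site coordinates (`site_start`, `site_end`, filled in by
#'   [synthesize_utrs()]).
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(sim_seed(config, "truth"))
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  grid <- expand.grid(gene = genes, species = config$species_list,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$species, grid$gene), , drop = FALSE]
  p <- c(direct_target = config$frac_direct,
         indirect_responder = config$frac_indirect)
  p <- c(p, null = 1 - sum(p))
  grid$class <- sample(names(p), nrow(grid), replace = TRUE, prob = p)
  direct <- grid$class == "direct_target"
  responder <- grid$class != "null"
  grid$effect_screen_log2fc <- ifelse(responder, config$effect_log2fc, 0)
  grid$effect_pulldown_log2 <- ifelse(direct, config$pulldown_log2_enrichment, 0)
  grid$effect_luciferase <- ifelse(direct, config$luciferase_repression, 1)
  grid$site_start <- NA_integer_
  grid$site_end <- NA_integer_
  rownames(grid) <- NULL
  class(grid) <- c("truth_table", "data.frame")
  grid
}

## One random UTR from the uniform base model (RNA alphabet).
random_utr <- function(length) {
  paste(sample(c("A", "C", "G", "U"), length, replace = TRUE), collapse = "")
}

#' Synthesize UTR sequences with planted seed sites
#'
#' Direct-target UTRs receive the miRNA's 7-nt seed-binding sequence
#' (reverse complement of positions 2-8) planted at a random position; the
#' recorded interval is stored in the truth table. UTRs of null genes and
#' indirect responders are rejection-sampled until they contain no site of
#' any type, so ground truth is unambiguous. Set `reject_background = FALSE`
#' to keep raw uniform-model background (used to study chance match rates).
#'
#' @param truth A [generate_truth()] table.
#' @param mirna A [mirna_sequence()].
#' @param config The [simulation_config()] used for `truth`.
#' @param reject_background Rejection-sample background UTRs to zero sites
#'   (default `TRUE`).
#' @return List with `utrs` (named character vector, `"gene|species"`) and
#'   `truth` (the input table with planted site coordinates filled in).
#' @export
synthesize_utrs <- function(truth, mirna, config, reject_background = TRUE) {
  stopifnot(inherits(truth, "truth_table"), inherits(mirna, "mirna_sequence"),
            inherits(config, "simulation_config"))
  L <- config$utr_length
  site <- mirna$seed_binding
  k <- nchar(site)
  if (L < k + 2L) stop("utr_length too short to host a seed site", call. = FALSE)
  set.seed(sim_seed(config, "utrs"))
  utrs <- character(nrow(truth))
  names(utrs) <- paste(truth$gene, truth$species, sep = "|")
  for (i in seq_len(nrow(truth))) {
    if (truth$class[i] == "direct_target") {
      u <- random_utr(L)
      pos <- sample.int(L - k + 1L, 1L)            # 1-based insertion start
      substr(u, pos, pos + k - 1L) <- site
      truth$site_start[i] <- pos - 1L
      truth$site_end[i] <- pos - 1L + k
      utrs[i] <- u
    } else {
      repeat {
        u <- random_utr(L)
        if (!reject_background ||
            nrow(find_seed_sites(u, mirna, SITE_TYPES)) == 0L) break
      }
      utrs[i] <- u
    }
  }
  list(utrs = utrs, truth = truth)
}

#' Simulate the gain/loss-of-function qPCR screen
#'
#' For every gene, species, and perturbation mode (GOF, LOF) the table holds
#' replicate target and reference Ct values under three conditions: `mock`,
#' `negative_control`, and `treatment`. Screen responders shift the
#' treatment target Ct by `+effect_log2fc` under GOF (repression: fewer
#' transcripts, later crossing) and `-effect_log2fc` under LOF
#' (derepression). Gaussian noise of sd `noise_sd_ct` is applied to the
#' target Ct only, so the per-replicate delta-Ct sd equals `noise_sd_ct`;
#' the reference Ct is a fixed housekeeping baseline.
#'
#' @param truth A [generate_truth()] table.
#' @param config The matching [simulation_config()].
#' @return Data frame: `gene`, `species`, `mode`, `condition`, `replicate`,
#'   `ct_target`, `ct_reference`.
#' @export
simulate_qpcr_screen <- function(truth, config) {
  stopifnot(inherits(truth, "truth_table"), inherits(config, "simulation_config"))
  set.seed(sim_seed(config, "screen"))
  n <- config$n_replicates
  base_ct <- stats::setNames(stats::runif(length(unique(truth$gene)), 20, 26),
                             sort(unique(truth$gene)))
  grid <- expand.grid(replicate = seq_len(n),
                      condition = c("mock", "negative_control", "treatment"),
                      mode = c("GOF", "LOF"),
                      row = seq_len(nrow(truth)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(gene = truth$gene[grid$row],
                    species = truth$species[grid$row],
                    mode = grid$mode, condition = grid$condition,
                    replicate = grid$replicate, stringsAsFactors = FALSE)
  shift <- ifelse(out$condition == "treatment",
                  ifelse(out$mode == "GOF", 1, -1) *
                    truth$effect_screen_log2fc[grid$row],
                  0)
  mu <- base_ct[out$gene] + shift
  out$ct_target <- stats::rnorm(nrow(out), mu, config$noise_sd_ct)
  out$ct_reference <- 15
  out <- out[order(out$species, out$gene, out$mode, out$condition, out$replicate), ]
  rownames(out) <- NULL
  out
}

#' Simulate the biotinylated-miRNA pull-down
#'
#' Replicate Ct values for each gene under two baits (`mirna`,
#' `control_mirna`), reference-normalized against a housekeeping gene.
#' Direct targets only are enriched: their target Ct under the miRNA bait is
#' lowered by `pulldown_log2_enrichment` cycles. Indirect responders and
#' null genes are centred at zero enrichment, which is what lets the
#' pull-down separate direct binding from downstream response.
#'
#' @inheritParams simulate_qpcr_screen
#' @return Data frame: `gene`, `species`, `bait`, `replicate`, `ct_target`,
#'   `ct_reference`.
#' @export
simulate_pulldown <- function(truth, config) {
  stopifnot(inherits(truth, "truth_table"), inherits(config, "simulation_config"))
  set.seed(sim_seed(config, "pulldown"))
  n <- config$n_replicates
  base_ct <- stats::setNames(stats::runif(length(unique(truth$gene)), 22, 28),
                             sort(unique(truth$gene)))
  grid <- expand.grid(replicate = seq_len(n),
                      bait = c("mirna", "control_mirna"),
                      row = seq_len(nrow(truth)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(gene = truth$gene[grid$row],
                    species = truth$species[grid$row],
                    bait = grid$bait, replicate = grid$replicate,
                    stringsAsFactors = FALSE)
  shift <- ifelse(out$bait == "mirna",
                  -truth$effect_pulldown_log2[grid$row], 0)
  out$ct_target <- stats::rnorm(nrow(out), base_ct[out$gene] + shift,
                                config$noise_sd_ct)
  out$ct_reference <- 15
  out <- out[order(out$species, out$gene, out$bait, out$replicate), ]
  rownames(out) <- NULL
  out
}

#' Simulate dual-luciferase reporter readings
#'
#' One construct per gene-species UTR; each well carries a Renilla reading
#' (the UTR reporter) and a firefly reading (the transfection control).
#' Both signals share a per-well scale factor, so their ratio is invariant
#' to well-to-well transfection efficiency. Under the miRNA duplex, direct
#' constructs' Renilla signal is scaled by `luciferase_repression`;
#' multiplicative log-normal noise is applied to the reporter (Renilla)
#' reading so the normalized ratio has coefficient of variation
#' `luciferase_cv`.
#'
#' @inheritParams simulate_qpcr_screen
#' @return Data frame: `construct` (`"gene|species"`), `condition`
#'   (`mirna_duplex`/`scrambled`), `replicate`, `renilla`, `firefly`.
#' @export
simulate_luciferase <- function(truth, config) {
  stopifnot(inherits(truth, "truth_table"), inherits(config, "simulation_config"))
  set.seed(sim_seed(config, "luciferase"))
  n <- config$n_replicates
  grid <- expand.grid(replicate = seq_len(n),
                      condition = c("mirna_duplex", "scrambled"),
                      row = seq_len(nrow(truth)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(construct = paste(truth$gene[grid$row],
                                      truth$species[grid$row], sep = "|"),
                    condition = grid$condition, replicate = grid$replicate,
                    stringsAsFactors = FALSE)
  activity <- ifelse(out$condition == "mirna_duplex",
                     truth$effect_luciferase[grid$row], 1)
  well <- exp(stats::rnorm(nrow(out), 0, 0.2))       # shared transfection factor
  sdlog <- sqrt(log(1 + config$luciferase_cv^2))
  out$firefly <- 1000 * well
  out$renilla <- 500 * well * activity * stats::rlnorm(nrow(out), 0, sdlog)
  out <- out[order(out$construct, out$condition, out$replicate), ]
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic dataset bundle
#'
#' Runs all sub-generators and returns the bundle consumed by
#' [run_pipeline()], including an identity orthology map and a two-class
#' functional annotation (alternating apoptosis / cell-cycle regulators, so
#' network-level summaries are exercised).
#'
#' @param config A [simulation_config()].
#' @param mirna A [mirna_sequence()]; defaults to miR-125b.
#' @return List of class `"mirvalid_bundle"`: `mirna`, `utrs`, `truth`,
#'   `pathway` (annotation table), `orthology`, `screen_ct`, `pulldown_ct`,
#'   `luciferase`.
#' @export
simulate_dataset <- function(config = simulation_config(),
                             mirna = mirna_sequence("miR-125b",
                                                    "UCCCUGAGACCCUAACUUGUGA")) {
  truth <- generate_truth(config)
  syn <- synthesize_utrs(truth, mirna, config)
  truth <- syn$truth
  genes <- sort(unique(truth$gene))
  pathway <- data.frame(
    canonical = genes,
    functional_class = rep(c("apoptosis_regulator", "cell_cycle_regulator"),
                           length.out = length(genes)),
    process_effect = rep(c("promotes", "promotes", "inhibits", "inhibits"),
                         length.out = length(genes)),
    stringsAsFactors = FALSE
  )
  orthology <- expand.grid(species = config$species_list, symbol = genes,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  orthology$canonical <- orthology$symbol
  orthology <- orthology[order(orthology$species, orthology$symbol), ]
  rownames(orthology) <- NULL
  structure(
    list(mirna = mirna, utrs = syn$utrs, truth = truth, pathway = pathway,
         orthology = orthology,
         screen_ct = simulate_qpcr_screen(truth, config),
         pulldown_ct = simulate_pulldown(truth, config),
         luciferase = simulate_luciferase(truth, config),
         config = config),
    class = "mirvalid_bundle"
  )
}

#' Write a synthetic bundle to disk
#'
#' UTRs are written as FASTA with `"gene|species"` headers; all tables as
#' TSV with fixed column names.
#'
#' @param bundle A [simulate_dataset()] bundle.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_dataset <- function(bundle, dir) {
  stopifnot(inherits(bundle, "mirvalid_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    utrs = file.path(dir, "utrs.fa"),
    truth = file.path(dir, "truth.tsv"),
    pathway = file.path(dir, "pathway.tsv"),
    orthology = file.path(dir, "orthology.tsv"),
    screen_ct = file.path(dir, "screen_ct.tsv"),
    pulldown_ct = file.path(dir, "pulldown_ct.tsv"),
    luciferase = file.path(dir, "luciferase.tsv"),
    mirna = file.path(dir, "mirna.fa")
  )
  write_utr_fasta(bundle$utrs, paths[["utrs"]])
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(stats::setNames(bundle$mirna$sequence,
                                           bundle$mirna$name)),
    paths[["mirna"]])
  for (nm in c("truth", "pathway", "orthology", "screen_ct", "pulldown_ct",
               "luciferase")) {
    utils::write.table(as.data.frame(bundle[[nm]]), paths[[nm]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
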
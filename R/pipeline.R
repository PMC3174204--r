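#' Pipeline configuration
#'
#' Paths to the input files consumed by [load_inputs()], plus thresholds
#' and the master seed. All files are plain text: FASTA for sequences, TSV
#' with fixed column names for tables.
#'
#' @param utr_fasta UTR FASTA (headers `"gene|species"`).
#' @param mirna_fasta Single-record FASTA with the mature miRNA sequence.
#' @param pathway_tsv Pathway/annotation TSV: `canonical`,
#'   `functional_class`, `process_effect`.
#' @param orthology_tsv Orthology TSV: `species`, `symbol`, `canonical`.
#' @param screen_tsv Screen Ct TSV: `gene`, `species`, `mode`, `condition`,
#'   `replicate`, `ct_target`, `ct_reference`.
#' @param pulldown_tsv Pull-down Ct TSV: `gene`, `species`, `bait`,
#'   `replicate`, `ct_target`, `ct_reference`.
#' @param luciferase_tsv Luciferase well TSV: `construct`, `condition`,
#'   `replicate`, `renilla`, `firefly`.
#' @param thresholds A [default_thresholds()] object.
#' @param rng_seed Master seed recorded in the report provenance.
#' @param out_dir Output directory for [write_report()].
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(utr_fasta, mirna_fasta, pathway_tsv,
                            orthology_tsv, screen_tsv, pulldown_tsv,
                            luciferase_tsv,
                            thresholds = default_thresholds(),
                            rng_seed = 1L, out_dir = ".") {
  cfg <- list(utr_fasta = utr_fasta, mirna_fasta = mirna_fasta,
              pathway_tsv = pathway_tsv, orthology_tsv = orthology_tsv,
              screen_tsv = screen_tsv, pulldown_tsv = pulldown_tsv,
              luciferase_tsv = luciferase_tsv, thresholds = thresholds,
              rng_seed = as.integer(rng_seed), out_dir = out_dir)
  files <- unlist(cfg[grepl("_fasta$|_tsv$", names(cfg))])
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

check_columns <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop("file '", file, "' lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("file '", file, "' is empty", call. = FALSE)
  invisible(df)
}

#' Load and schema-check a dataset bundle from disk
#'
#' @param config A [pipeline_config()].
#' @return A `"mirvalid_bundle"` as produced by [simulate_dataset()] (minus
#'   the truth table, which real data does not have).
#' @export
load_inputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  utrs <- read_utr_fasta(config$utr_fasta)
  mir_set <- Biostrings::readBStringSet(config$mirna_fasta)
  if (length(mir_set) != 1L) {
    stop("miRNA FASTA must contain exactly one record", call. = FALSE)
  }
  mirna <- mirna_sequence(names(mir_set)[1], as.character(mir_set[[1]]))
  pathway <- check_columns(utils::read.delim(config$pathway_tsv,
                                             stringsAsFactors = FALSE),
                           c("canonical", "functional_class", "process_effect"),
                           config$pathway_tsv)
  orthology <- validate_orthology(
    check_columns(utils::read.delim(config$orthology_tsv,
                                    stringsAsFactors = FALSE),
                  c("species", "symbol", "canonical"), config$orthology_tsv))
  screen_ct <- check_columns(utils::read.delim(config$screen_tsv,
                                               stringsAsFactors = FALSE),
                             c("gene", "species", "mode", "condition",
                               "replicate", "ct_target", "ct_reference"),
                             config$screen_tsv)
  pulldown_ct <- check_columns(utils::read.delim(config$pulldown_tsv,
                                                 stringsAsFactors = FALSE),
                               c("gene", "species", "bait", "replicate",
                                 "ct_target", "ct_reference"),
                               config$pulldown_tsv)
  luciferase <- check_columns(utils::read.delim(config$luciferase_tsv,
                                                stringsAsFactors = FALSE),
                              c("construct", "condition", "replicate",
                                "renilla", "firefly"), config$luciferase_tsv)
  structure(
    list(mirna = mirna, utrs = utrs, truth = NULL, pathway = pathway,
         orthology = orthology, screen_ct = screen_ct,
         pulldown_ct = pulldown_ct, luciferase = luciferase,
         config = config),
    class = "mirvalid_bundle"
  )
}

#' Screen calls for every gene-species in a Ct table
#'
#' Computes, per gene, species and perturbation mode, the delta-delta-Ct
#' fold change of `treatment` against `negative_control` (the mock fold
#' change is carried along as a sanity column) and combines the GOF and
#' LOF arms into a gene-level screen call.
#'
#' @param screen_ct Screen Ct table (see [pipeline_config()]).
#' @param thresholds A [default_thresholds()] object.
#' @param genes Optional gene subset (per species, a named list of gene
#'   vectors keyed by species; or a character vector applied to all).
#' @return List with `calls` (gene-level `"assay_call"`s) and `details`
#'   (data frame of per-mode fold changes, p-values and mock fold changes).
#' @export
run_screen_calls <- function(screen_ct, thresholds = default_thresholds(),
                             genes = NULL) {
  units <- unique(screen_ct[c("gene", "species")])
  units <- restrict_units(units, genes)
  calls <- vector("list", nrow(units))
  details <- vector("list", nrow(units))
  for (i in seq_len(nrow(units))) {
    g <- units$gene[i]; sp <- units$species[i]
    rows <- screen_ct[screen_ct$gene == g & screen_ct$species == sp, ]
    per_mode <- list()
    for (mode in intersect(c("GOF", "LOF"), unique(rows$mode))) {
      mr <- rows[rows$mode == mode, ]
      fc <- ddct_fold_change(mr[mr$condition == "treatment", ],
                             mr[mr$condition == "negative_control", ],
                             gene = g, species = sp, assay = "screen")
      mock_fc <- ddct_fold_change(mr[mr$condition == "treatment", ],
                                  mr[mr$condition == "mock", ],
                                  gene = g, species = sp, assay = "screen")
      per_mode[[mode]] <- list(call = screen_call(fc, mode, thresholds),
                               fc = fc, mock_fc = mock_fc)
    }
    calls[[i]] <- screen_gene_call(per_mode$GOF$call, per_mode$LOF$call)
    details[[i]] <- do.call(rbind, lapply(names(per_mode), function(mode) {
      pm <- per_mode[[mode]]
      data.frame(gene = g, species = sp, mode = mode,
                 linear_fc = pm$fc$linear_fc, log2_fc = pm$fc$log2_fc,
                 p_value = pm$fc$p_value, mock_linear_fc = pm$mock_fc$linear_fc,
                 passed = pm$call$passed, stringsAsFactors = FALSE)
    }))
  }
  list(calls = calls, details = do.call(rbind, details))
}

#' Pull-down enrichment calls for a Ct table
#'
#' @param pulldown_ct Pull-down Ct table (see [pipeline_config()]).
#' @inheritParams run_screen_calls
#' @return List with `calls` and `details` as in [run_screen_calls()].
#' @export
run_pulldown_calls <- function(pulldown_ct, thresholds = default_thresholds(),
                               genes = NULL) {
  units <- unique(pulldown_ct[c("gene", "species")])
  units <- restrict_units(units, genes)
  calls <- vector("list", nrow(units))
  for (i in seq_len(nrow(units))) {
    g <- units$gene[i]; sp <- units$species[i]
    rows <- pulldown_ct[pulldown_ct$gene == g & pulldown_ct$species == sp, ]
    calls[[i]] <- pulldown_enrichment_call(
      rows[rows$bait == "mirna", ], rows[rows$bait == "control_mirna", ],
      gene = g, species = sp, thresholds = thresholds)
  }
  details <- do.call(rbind, lapply(calls, function(cl) {
    data.frame(gene = cl$gene, species = cl$species,
               log2_fc = cl$stats$log2_fc, p_value = cl$stats$p_value,
               passed = cl$passed, stringsAsFactors = FALSE)
  }))
  list(calls = calls, details = details)
}

#' Luciferase repression calls for a well table
#'
#' @param luciferase Well table (see [pipeline_config()]); constructs are
#'   `"gene|species"`.
#' @inheritParams run_screen_calls
#' @return List with `calls` and `details`.
#' @export
run_luciferase_calls <- function(luciferase, thresholds = default_thresholds(),
                                 genes = NULL) {
  ids <- parse_utr_headers(unique(luciferase$construct))
  units <- data.frame(gene = ids$gene, species = ids$species,
                      construct = unique(luciferase$construct),
                      stringsAsFactors = FALSE)
  keep <- restrict_units(units[c("gene", "species")], genes)
  units <- units[paste(units$gene, units$species) %in%
                   paste(keep$gene, keep$species), , drop = FALSE]
  calls <- vector("list", nrow(units))
  for (i in seq_len(nrow(units))) {
    rows <- luciferase[luciferase$construct == units$construct[i], ]
    res <- luciferase_percent_activity(
      rows[rows$condition == "mirna_duplex", ],
      rows[rows$condition == "scrambled", ],
      construct = units$construct[i])
    calls[[i]] <- luciferase_repression_call(res, gene = units$gene[i],
                                             species = units$species[i],
                                             thresholds = thresholds)
  }
  details <- do.call(rbind, lapply(calls, function(cl) {
    data.frame(gene = cl$gene, species = cl$species,
               percent = cl$stats$percent, p_value = cl$stats$p_value,
               passed = cl$passed, stringsAsFactors = FALSE)
  }))
  list(calls = calls, details = details)
}

## Subset a gene-species unit table by a per-species list (or plain vector)
## of genes; NULL keeps everything.
restrict_units <- function(units, genes) {
  units <- units[order(units$species, units$gene), , drop = FALSE]
  rownames(units) <- NULL
  if (is.null(genes)) return(units)
  if (!is.list(genes)) {
    return(units[units$gene %in% genes, , drop = FALSE])
  }
  keep <- mapply(function(g, sp) {
    !is.null(genes[[sp]]) && g %in% genes[[sp]]
  }, units$gene, units$species)
  units[keep, , drop = FALSE]
}

#' Run the full screen-and-validate pipeline
#'
#' Executes the workflow in order: site prediction on the UTRs, the
#' GOF/LOF expression screen, the pull-down (screen passers only, when
#' gated), the luciferase assay (pull-down passers only, when gated),
#' evidence integration with tiering and the two-assay retention filter,
#' and feed-forward-loop analysis of the resulting signed network.
#'
#' @param bundle A `"mirvalid_bundle"` ([simulate_dataset()] or
#'   [load_inputs()]).
#' @param thresholds A [default_thresholds()] object.
#' @param gate_workflow Restrict each assay to the genes that passed the
#'   previous one, as in the experimental workflow (default `TRUE`). When
#'   `FALSE` every assay is evaluated for every predicted gene.
#' @param allowed_types Site types accepted as a prediction.
#' @return List of class `"mirvalid_report"`.
#' @export
run_pipeline <- function(bundle, thresholds = default_thresholds(),
                         gate_workflow = TRUE,
                         allowed_types = c("8mer", "7mer-m8", "7mer-A1")) {
  stopifnot(inherits(bundle, "mirvalid_bundle"))
  sites <- scan_utr_sites(bundle$utrs, bundle$mirna, allowed_types)
  predicted <- predict_pathway_targets(sites, bundle$pathway$canonical)

  screen <- run_screen_calls(bundle$screen_ct, thresholds, genes = predicted)
  screen_pass <- lapply(split(screen$details[screen$details$passed, ],
                              screen$details$species[screen$details$passed]),
                        function(d) unique(d$gene))
  pd_genes <- if (gate_workflow) screen_pass else predicted
  pulldown <- run_pulldown_calls(bundle$pulldown_ct, thresholds,
                                 genes = pd_genes)
  pd_pass <- split(pulldown$details$gene[pulldown$details$passed],
                   pulldown$details$species[pulldown$details$passed])
  luc_genes <- if (gate_workflow) pd_pass else predicted
  luciferase <- run_luciferase_calls(bundle$luciferase, thresholds,
                                     genes = luc_genes)

  call_table <- as_call_table(c(screen$calls, pulldown$calls,
                                luciferase$calls))
  validation <- validate_targets(call_table, bundle$orthology,
                                 enforce_workflow = gate_workflow)

  network <- NULL
  if (validation$n_validated > 0L) {
    edges <- build_target_network(validation$validated, bundle$pathway,
                                  mirna_name = bundle$mirna$name)
    ffls <- enumerate_ffls(edges)
    conservation <- if (length(validation$per_species) >= 2L) {
      network_conservation_summary(validation$per_species, bundle$pathway)
    }
    network <- list(edges = edges, ffls = ffls, conservation = conservation)
  }

  cfg <- bundle$config
  seed <- if (!is.null(cfg$rng_seed)) cfg$rng_seed else NA_integer_
  structure(
    list(
      sites = sites, predicted = predicted,
      screen = screen$details, pulldown = pulldown$details,
      luciferase = luciferase$details,
      calls = call_table, validation = validation, network = network,
      provenance = list(
        package_version = as.character(utils::packageVersion("mirvalid")),
        rng_seed = seed,
        config_hash = config_hash(cfg),
        thresholds = unclass(thresholds),
        screen_denominator = "negative_control (mock carried as sanity column)"
      )
    ),
    class = "mirvalid_report"
  )
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.mirvalid_report <- function(x, ...) {
  cat("<mirvalid_report>\n")
  cat("  predicted targets: ",
      paste(sprintf("%s=%d", names(x$predicted),
                    lengths(x$predicted)), collapse = ", "), "\n")
  cat("  validated targets: ", x$validation$n_validated, "\n")
  if (!is.null(x$network)) {
    inc <- sum(x$network$ffls$coherence == "incoherent")
    cat("  feed-forward loops:", nrow(x$network$ffls),
        sprintf("(%d incoherent)", inc), "\n")
    if (!is.null(x$network$conservation)) {
      cat("  network-level conservation:",
          x$network$conservation$network_conserved, "\n")
    }
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' `"json"` writes a single machine-readable `report.json` (including the
#' provenance block); `"tsv"` writes one table per stage, round-trippable
#' through `read.delim()`.
#'
#' @param report A `"mirvalid_report"`.
#' @param dir Output directory (created if needed).
#' @param format `"json"`, `"tsv"`, or both.
#' @return Invisibly, the written paths.
#' @export
write_report <- function(report, dir, format = c("json", "tsv")) {
  stopifnot(inherits(report, "mirvalid_report"))
  bad <- setdiff(format, c("json", "tsv"))
  if (length(bad)) stop("unknown report format: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if ("json" %in% format) {
    p <- file.path(dir, "report.json")
    payload <- list(
      provenance = report$provenance,
      predicted = report$predicted,
      n_sites = nrow(report$sites),
      screen = report$screen, pulldown = report$pulldown,
      luciferase = report$luciferase,
      evidence_matrix = as.data.frame(report$validation$matrix),
      tiers = as.data.frame(report$validation$tiers),
      validated = report$validation$validated,
      n_validated = report$validation$n_validated,
      per_species = report$validation$per_species,
      jaccard = if (!is.null(report$validation$overlap))
        report$validation$overlap$jaccard,
      ffls = if (!is.null(report$network)) report$network$ffls,
      network_conserved = if (!is.null(report$network) &&
                              !is.null(report$network$conservation))
        report$network$conservation$network_conserved
    )
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    paths <- c(paths, json = p)
  }
  if ("tsv" %in% format) {
    tables <- list(sites = report$sites, screen = report$screen,
                   pulldown = report$pulldown, luciferase = report$luciferase,
                   calls = report$calls,
                   evidence_matrix = as.data.frame(report$validation$matrix),
                   tiers = as.data.frame(report$validation$tiers))
    if (!is.null(report$network)) tables$ffls <- report$network$ffls
    for (nm in names(tables)) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- c(paths, stats::setNames(p, nm))
    }
  }
  invisible(paths)
}
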
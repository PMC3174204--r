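#' Read an orthology table
#'
#' Maps species-specific gene symbols to one canonical identifier
#' (human-style symbol) so cross-species evidence can be collapsed.
#'
#' @param path TSV with columns `species`, `symbol`, `canonical`.
#' @return Data frame with those three columns.
#' @export
read_orthology <- function(path) {
  orth <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_orthology(orth)
  orth
}

validate_orthology <- function(orth) {
  need <- c("species", "symbol", "canonical")
  miss <- setdiff(need, names(orth))
  if (length(miss)) {
    stop("orthology table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(orth$species, orth$symbol)
  if (anyDuplicated(key)) {
    stop("orthology map is not injective per species; duplicated: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  invisible(orth)
}

map_canonical <- function(species, symbol, orthology) {
  idx <- match(paste(species, symbol), paste(orthology$species, orthology$symbol))
  if (anyNA(idx)) {
    offenders <- unique(paste0(species, ":", symbol)[is.na(idx)])
    stop("gene symbol(s) missing from the orthology map: ",
         paste(offenders, collapse = ", "), call. = FALSE)
  }
  orthology$canonical[idx]
}

ASSAYS <- c("screen", "pulldown", "luciferase")

#' Assemble the gene x species x assay evidence matrix
#'
#' Collapses species symbols to canonical identifiers and pivots the calls
#' into one row per canonical gene and species with one column per assay,
#' each cell `"pass"`, `"fail"`, or `"not_tested"`. Duplicate calls that
#' agree are collapsed; duplicates that conflict are an error. By default
#' the workflow invariant that only screen-passers enter the pull-down is
#' enforced; disable it for data generated outside the gated workflow.
#'
#' @param calls Data frame with columns `species`, `symbol`, `assay`
#'   (`screen`/`pulldown`/`luciferase`), `result` (`pass`/`fail`), e.g. from
#'   [as_call_table()].
#' @param orthology Orthology table (`species`, `symbol`, `canonical`)
#'   covering every symbol in `calls`.
#' @param enforce_workflow Error when a pull-down call exists without a
#'   screen pass (default `TRUE`).
#' @return Data frame of class `"evidence_matrix"`: `canonical`, `species`,
#'   `screen`, `pulldown`, `luciferase`.
#' @export
build_evidence_matrix <- function(calls, orthology, enforce_workflow = TRUE) {
  stopifnot(is.data.frame(calls))
  need <- c("species", "symbol", "assay", "result")
  miss <- setdiff(need, names(calls))
  if (length(miss)) {
    stop("calls table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  validate_orthology(orthology)
  if (!all(calls$assay %in% ASSAYS)) {
    stop("unknown assay value(s): ",
         paste(setdiff(unique(calls$assay), ASSAYS), collapse = ", "),
         call. = FALSE)
  }
  if (!all(calls$result %in% c("pass", "fail"))) {
    stop("call results must be 'pass' or 'fail'", call. = FALSE)
  }
  calls$canonical <- map_canonical(calls$species, calls$symbol, orthology)
  key <- paste(calls$canonical, calls$species, calls$assay)
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    per_key <- tapply(calls$result[dup], key[dup],
                      function(r) length(unique(r)))
    if (any(per_key > 1L)) {
      stop("conflicting duplicate calls for: ",
           paste(names(per_key)[per_key > 1L], collapse = "; "), call. = FALSE)
    }
    calls <- calls[!duplicated(key), , drop = FALSE]
  }
  units <- unique(calls[c("canonical", "species")])
  units <- units[order(units$canonical, units$species), , drop = FALSE]
  mat <- units
  for (a in ASSAYS) {
    idx <- match(paste(units$canonical, units$species),
                 paste(calls$canonical[calls$assay == a],
                       calls$species[calls$assay == a]))
    mat[[a]] <- ifelse(is.na(idx), "not_tested", calls$result[calls$assay == a][idx])
  }
  bad <- enforce_workflow & mat$pulldown != "not_tested" & mat$screen != "pass"
  if (any(bad)) {
    stop("workflow violation: pull-down tested without a screen pass for ",
         paste(paste0(mat$canonical[bad], ":", mat$species[bad]), collapse = ", "),
         call. = FALSE)
  }
  rownames(mat) <- NULL
  class(mat) <- c("evidence_matrix", "data.frame")
  mat
}

#' Assign evidence tiers and the retention flag
#'
#' Per gene-species record, the tier counts assay passes (`not_tested`
#' counts as not passed): three passes give `red`, two `orange`, one
#' `yellow`; zero passes give `pink` when the gene is `red` in another
#' species and `none` otherwise. A gene is retained as a validated target
#' iff it passes at least 2 assays in at least one species.
#'
#' @param matrix An [build_evidence_matrix()] result.
#' @return Data frame of class `"tier_assignment"`: `canonical`, `species`,
#'   `n_pass`, `tier`, `retained` (gene-level flag, repeated per row).
#' @export
assign_tier <- function(matrix) {
  stopifnot(inherits(matrix, "evidence_matrix"))
  n_pass <- rowSums(cbind(matrix$screen == "pass",
                          matrix$pulldown == "pass",
                          matrix$luciferase == "pass"))
  tiers <- data.frame(canonical = matrix$canonical, species = matrix$species,
                      n_pass = as.integer(n_pass), stringsAsFactors = FALSE)
  red_genes <- unique(tiers$canonical[tiers$n_pass == 3L])
  tiers$tier <- ifelse(tiers$n_pass == 3L, "red",
                ifelse(tiers$n_pass == 2L, "orange",
                ifelse(tiers$n_pass == 1L, "yellow",
                ifelse(tiers$canonical %in% red_genes, "pink", "none"))))
  retained_genes <- unique(tiers$canonical[tiers$n_pass >= 2L])
  tiers$retained <- tiers$canonical %in% retained_genes
  class(tiers) <- c("tier_assignment", "data.frame")
  tiers
}

#' Validated target set
#'
#' The sorted set of canonical genes retained by the two-assay rule.
#'
#' @param tiers An [assign_tier()] result.
#' @return Character vector (lexicographic order).
#' @export
validated_target_set <- function(tiers) {
  stopifnot(inherits(tiers, "tier_assignment"))
  sort(unique(tiers$canonical[tiers$retained]))
}

#' Per-species validated target sets
#'
#' @param tiers An [assign_tier()] result.
#' @return Named list of sorted canonical gene vectors, one per species:
#'   the genes with >= 2 assay passes in that species.
#' @export
per_species_validated <- function(tiers) {
  stopifnot(inherits(tiers, "tier_assignment"))
  species <- sort(unique(tiers$species))
  out <- lapply(species, function(sp) {
    sort(unique(tiers$canonical[tiers$species == sp & tiers$n_pass >= 2L]))
  })
  names(out) <- species
  out
}

#' Cross-species overlap of validated targets
#'
#' @param tiers An [assign_tier()] result covering at least two species.
#' @return List with `per_species` (validated sets), `jaccard` (symmetric
#'   matrix of pairwise Jaccard indices on canonical identifiers), and
#'   `intersection` (genes validated in every species).
#' @export
cross_species_overlap <- function(tiers) {
  sets <- per_species_validated(tiers)
  if (length(sets) < 2L) {
    stop("cross-species overlap requires at least two species", call. = FALSE)
  }
  sp <- names(sets)
  jac <- matrix(1, length(sp), length(sp), dimnames = list(sp, sp))
  for (i in seq_along(sp)) for (j in seq_along(sp)) {
    if (i == j) next
    u <- length(union(sets[[i]], sets[[j]]))
    jac[i, j] <- if (u == 0L) 0 else length(intersect(sets[[i]], sets[[j]])) / u
  }
  list(per_species = sets, jaccard = jac,
       intersection = sort(Reduce(intersect, sets)))
}

#' Multi-assay target validation
#'
#' The central constructor: collapses assay calls through the orthology
#' map, builds the evidence matrix, assigns tiers, applies the two-assay
#' retention filter, and (for two or more species) computes cross-species
#' overlaps.
#'
#' @param calls Calls table (`species`, `symbol`, `assay`, `result`).
#' @param orthology Orthology table (`species`, `symbol`, `canonical`).
#' @param enforce_workflow Passed to [build_evidence_matrix()].
#' @return Object of class `"target_validation"` with elements `matrix`,
#'   `tiers`, `validated`, `per_species`, `overlap` (or `NULL` for a single
#'   species), and `n_validated`.
#' @examples
#' fx <- p53_fixture()
#' tv <- validate_targets(fx$calls, fx$orthology)
#' tv
#' @export
validate_targets <- function(calls, orthology, enforce_workflow = TRUE) {
  mat <- build_evidence_matrix(calls, orthology, enforce_workflow)
  tiers <- assign_tier(mat)
  validated <- validated_target_set(tiers)
  per_sp <- per_species_validated(tiers)
  overlap <- if (length(per_sp) >= 2L) cross_species_overlap(tiers) else NULL
  structure(
    list(matrix = mat, tiers = tiers, validated = validated,
         per_species = per_sp, overlap = overlap,
         n_validated = length(validated)),
    class = "target_validation"
  )
}

#' @export
print.target_validation <- function(x, ...) {
  cat("<target_validation>\n")
  cat("  species:          ", paste(names(x$per_species), collapse = ", "), "\n")
  cat("  gene-species records:", nrow(x$matrix), "\n")
  cat("  validated targets:", x$n_validated, "\n")
  if (!is.null(x$overlap)) {
    cat("  conserved in all species:",
        if (length(x$overlap$intersection)) paste(x$overlap$intersection, collapse = ", ")
        else "(none)", "\n")
  }
  invisible(x)
}

#' @export
summary.target_validation <- function(object, ...) {
  tiers <- object$tiers
  tab <- table(species = tiers$species,
               tier = factor(tiers$tier,
                             levels = c("red", "orange", "yellow", "pink", "none")))
  out <- list(tier_counts = tab, validated = object$validated,
              per_species = object$per_species,
              jaccard = if (!is.null(object$overlap)) object$overlap$jaccard)
  class(out) <- "summary.target_validation"
  out
}

#' @export
print.summary.target_validation <- function(x, ...) {
  cat("Evidence tiers by species:\n")
  print(x$tier_counts)
  cat("\nValidated targets (", length(x$validated), "):\n  ", sep = "")
  cat(paste(x$validated, collapse = ", "), "\n")
  if (!is.null(x$jaccard)) {
    cat("\nPairwise Jaccard overlap of per-species validated sets:\n")
    print(round(x$jaccard, 3))
  }
  invisible(x)
}

#' @export
plot.target_validation <- function(x, ...) {
  tiers <- x$tiers
  tiers <- tiers[tiers$tier != "none", , drop = FALSE]
  genes <- sort(unique(tiers$canonical), decreasing = TRUE)
  species <- sort(unique(tiers$species))
  lev <- c("pink", "yellow", "orange", "red")
  z <- matrix(NA_integer_, length(species), length(genes),
              dimnames = list(species, genes))
  for (i in seq_len(nrow(tiers))) {
    z[tiers$species[i], tiers$canonical[i]] <- match(tiers$tier[i], lev)
  }
  cols <- c("#F8BBD0", "#FFF176", "#FB8C00", "#C62828")
  op <- graphics::par(mar = c(4, 7, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_along(species), seq_along(genes), z,
                  col = cols, zlim = c(1, 4), axes = FALSE,
                  xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_along(species), labels = species, las = 1)
  graphics::axis(2, at = seq_along(genes), labels = genes, las = 2,
                 cex.axis = 0.7)
  graphics::title("Evidence tiers (red 3, orange 2, yellow 1, pink rescued)")
  invisible(x)
}
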
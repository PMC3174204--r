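#' Classify a feed-forward loop by its edge signs
#'
#' A feed-forward loop X -> Y -> Z with direct edge X -> Z is coherent when
#' the sign of the direct edge equals the product of the indirect-path
#' signs, and incoherent otherwise. Within each coherence family the type
#' number follows the standard 1-4 convention keyed on the indirect-path
#' signs `(sign_xy, sign_yz)`:
#'
#' | (X->Y, Y->Z) | coherent | incoherent |
#' |--------------|----------|------------|
#' | (+, +)       | type 1   | type 3     |
#' | (+, -)       | type 3   | type 1     |
#' | (-, +)       | type 4   | type 4     |
#' | (-, -)       | type 2   | type 2     |
#'
#' so the all-activation loop is coherent type 1 and the all-repression
#' loop (a repressor X silencing both a target Z and Y, another repressor
#' of Z) is incoherent type 2.
#'
#' @param sign_xy,sign_yz,sign_xz Edge signs, each `+1` or `-1`.
#' @return List with `coherence` (`"coherent"`/`"incoherent"`) and `type`
#'   (integer 1-4).
#' @examples
#' classify_ffl(-1, -1, -1)  # incoherent type 2
#' @export
classify_ffl <- function(sign_xy, sign_yz, sign_xz) {
  signs <- c(sign_xy, sign_yz, sign_xz)
  if (!all(signs %in% c(-1, 1))) {
    stop("edge signs must be +1 or -1", call. = FALSE)
  }
  coherent <- sign_xz == sign_xy * sign_yz
  key <- paste(sign_xy, sign_yz)
  type <- if (coherent) {
    switch(key, "1 1" = 1L, "-1 -1" = 2L, "1 -1" = 3L, "-1 1" = 4L)
  } else {
    switch(key, "1 -1" = 1L, "-1 -1" = 2L, "1 1" = 3L, "-1 1" = 4L)
  }
  list(coherence = if (coherent) "coherent" else "incoherent", type = type)
}

validate_edges <- function(edges) {
  need <- c("source", "target", "sign")
  miss <- setdiff(need, names(edges))
  if (length(miss)) {
    stop("edge table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(edges$sign %in% c(-1, 1))) {
    stop("edge signs must be +1 or -1", call. = FALSE)
  }
  if (any(edges$source == edges$target)) stop("self-loops are not allowed", call. = FALSE)
  if (anyDuplicated(paste(edges$source, edges$target))) {
    stop("at most one edge per ordered node pair", call. = FALSE)
  }
  invisible(edges)
}

#' Enumerate all feed-forward loops in a signed digraph
#'
#' Emits every ordered node triple (X, Y, Z) such that edges X->Y, Y->Z and
#' X->Z all exist, together with its classification.
#'
#' @param edges Data frame with columns `source`, `target`, `sign`
#'   (+1/-1); no self-loops, at most one edge per ordered pair.
#' @return Data frame: `x`, `y`, `z`, `sign_xy`, `sign_yz`, `sign_xz`,
#'   `coherence`, `type`.
#' @export
enumerate_ffls <- function(edges) {
  validate_edges(edges)
  empty <- data.frame(x = character(), y = character(), z = character(),
                      sign_xy = integer(), sign_yz = integer(),
                      sign_xz = integer(), coherence = character(),
                      type = integer(), stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) return(empty)
  sign_of <- stats::setNames(edges$sign, paste(edges$source, edges$target,
                                               sep = "\r"))
  out_nbrs <- split(edges$target, edges$source)
  rows <- list()
  for (x in names(out_nbrs)) {
    for (y in out_nbrs[[x]]) {
      zs <- out_nbrs[[y]]
      if (is.null(zs)) next
      for (z in zs) {
        if (z == x) next
        sxz <- unname(sign_of[paste(x, z, sep = "\r")])
        if (is.na(sxz)) next
        sxy <- unname(sign_of[paste(x, y, sep = "\r")])
        syz <- unname(sign_of[paste(y, z, sep = "\r")])
        cls <- classify_ffl(sxy, syz, sxz)
        rows[[length(rows) + 1L]] <- data.frame(
          x = x, y = y, z = z, sign_xy = sxy, sign_yz = syz, sign_xz = sxz,
          coherence = cls$coherence, type = cls$type, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$x, out$y, out$z), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the signed miRNA-gene-process network
#'
#' Edges: the miRNA represses every validated gene (sign -1); each gene
#' promotes (+1) or inhibits (-1) its annotated cellular process. With
#' `add_process_edges = TRUE` a direct miRNA -| process edge (sign -1) is
#' added for every process that at least one validated gene promotes,
#' closing the loops into the feed-forward structure in which the miRNA
#' represses a process both directly (through its promoters) and through
#' repressors of that process.
#'
#' @param validated Character vector of validated canonical genes.
#' @param annotations Data frame with columns `canonical`,
#'   `functional_class` (`apoptosis_regulator`/`cell_cycle_regulator`),
#'   `process_effect` (`promotes`/`inhibits`).
#' @param mirna_name Node id of the miRNA (default `"miRNA"`).
#' @param add_process_edges Add the direct miRNA -> process edges.
#' @return Signed edge table (`source`, `target`, `sign`).
#' @export
build_target_network <- function(validated, annotations,
                                 mirna_name = "miRNA",
                                 add_process_edges = TRUE) {
  ann <- check_annotations(validated, annotations)
  process <- ifelse(ann$functional_class == "apoptosis_regulator",
                    "apoptosis", "cell_cycle_arrest")
  edges <- rbind(
    data.frame(source = mirna_name, target = ann$canonical, sign = -1L,
               stringsAsFactors = FALSE),
    data.frame(source = ann$canonical, target = process,
               sign = ifelse(ann$process_effect == "promotes", 1L, -1L),
               stringsAsFactors = FALSE)
  )
  if (add_process_edges) {
    promoted <- unique(process[ann$process_effect == "promotes"])
    if (length(promoted)) {
      edges <- rbind(edges, data.frame(source = mirna_name, target = promoted,
                                       sign = -1L, stringsAsFactors = FALSE))
    }
  }
  rownames(edges) <- NULL
  validate_edges(edges)
}

check_annotations <- function(validated, annotations) {
  need <- c("canonical", "functional_class", "process_effect")
  miss <- setdiff(need, names(annotations))
  if (length(miss)) {
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(annotations$canonical)) {
    stop("each gene must be annotated exactly once", call. = FALSE)
  }
  unann <- setdiff(validated, annotations$canonical)
  if (length(unann)) {
    stop("validated gene(s) lack a functional annotation: ",
         paste(unann, collapse = ", "), call. = FALSE)
  }
  annotations[match(validated, annotations$canonical), , drop = FALSE]
}

#' Network-level vs gene-level conservation summary
#'
#' Regulation is conserved at the network level when every species retains
#' at least one validated gene in each functional class, even if the
#' individual genes differ; gene-level conservation is the (typically much
#' smaller) set of genes validated in every species.
#'
#' @param validated_sets Named list of per-species validated canonical gene
#'   vectors (e.g. from [per_species_validated()]).
#' @param annotations Annotation table as in [build_target_network()].
#' @return List with `class_counts` (species x class matrix),
#'   `network_conserved` flag, `gene_level_conserved` genes, and `jaccard`
#'   (pairwise Jaccard matrix).
#' @export
network_conservation_summary <- function(validated_sets, annotations) {
  stopifnot(is.list(validated_sets), !is.null(names(validated_sets)))
  all_genes <- sort(unique(unlist(validated_sets)))
  ann <- check_annotations(all_genes, annotations)
  classes <- sort(unique(ann$functional_class))
  sp <- sort(names(validated_sets))
  counts <- matrix(0L, length(sp), length(classes),
                   dimnames = list(sp, classes))
  for (s in sp) {
    g <- validated_sets[[s]]
    cls <- ann$functional_class[match(g, ann$canonical)]
    tab <- table(factor(cls, levels = classes))
    counts[s, ] <- as.integer(tab)
  }
  jac <- matrix(1, length(sp), length(sp), dimnames = list(sp, sp))
  for (i in seq_along(sp)) for (j in seq_along(sp)) {
    if (i == j) next
    u <- length(union(validated_sets[[sp[i]]], validated_sets[[sp[j]]]))
    jac[i, j] <- if (u == 0L) 0 else
      length(intersect(validated_sets[[sp[i]]], validated_sets[[sp[j]]])) / u
  }
  list(
    class_counts = counts,
    network_conserved = all(counts > 0L),
    gene_level_conserved = sort(Reduce(intersect, validated_sets[sp])),
    jaccard = jac
  )
}
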
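#' Candidate binding-site patterns for a miRNA
#'
#' The canonical exact-match seed-site taxonomy, expressed as the target-strand
#' (3'UTR, 5'->3') patterns that base-pair with the miRNA:
#' \describe{
#'   \item{7mer-m8}{reverse complement of miRNA positions 2-8 (the 7-nt
#'     seed-binding sequence).}
#'   \item{7mer-A1}{reverse complement of miRNA positions 2-7, followed by an
#'     adenine opposite miRNA position 1.}
#'   \item{8mer}{both: the seed-binding sequence followed by the A1 adenine.}
#'   \item{perfect23}{reverse complement of the entire mature sequence
#'     (a perfect-match positive-control site).}
#' }
#'
#' @param mirna A [mirna_sequence()] object.
#' @return Named character vector of RNA patterns.
#' @keywords internal
site_patterns <- function(mirna) {
  stopifnot(inherits(mirna, "mirna_sequence"))
  seed_binding <- mirna$seed_binding                       # rc of 2-8
  rc27 <- reverse_complement_rna(substr(mirna$sequence, 2L, 7L))
  c(
    "8mer"      = paste0(seed_binding, "A"),
    "7mer-m8"   = seed_binding,
    "7mer-A1"   = paste0(rc27, "A"),
    "perfect23" = reverse_complement_rna(mirna$sequence)
  )
}

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "perfect23")

#' Find exact seed-match sites in a 3'UTR
#'
#' Scans a UTR for every exact occurrence of the allowed site-type patterns
#' (see [site_patterns()]). Matches of the same type may overlap; matches of
#' different types routinely overlap (an 8mer locus also contains a 7mer-m8).
#' Coordinates are 0-based, half-open, on the UTR sense strand.
#'
#' @param utr UTR sequence (character; DNA or RNA alphabet, `T`/`U`
#'   equivalent). An empty string yields zero sites.
#' @param mirna A [mirna_sequence()] object.
#' @param allowed_types Subset of `c("8mer", "7mer-m8", "7mer-A1",
#'   "perfect23")`.
#' @return A data.frame with columns `start`, `end` (0-based half-open),
#'   `site_type`, and `seed_binding_seq` (the miRNA's 7-nt seed-binding
#'   sequence, RNA), sorted by `start` then type.
#' @examples
#' mir <- mirna_sequence("ex", "UAGCUUAUCAGACUGAUGUUGA")
#' find_seed_sites("GGGAUAAGCUAGGG", mir, allowed_types = "7mer-m8")
#' @export
find_seed_sites <- function(utr, mirna,
                            allowed_types = c("8mer", "7mer-m8", "7mer-A1")) {
  stopifnot(inherits(mirna, "mirna_sequence"))
  allowed_types <- match.arg(allowed_types, SITE_TYPES, several.ok = TRUE)
  empty <- data.frame(start = integer(), end = integer(),
                      site_type = character(), seed_binding_seq = character(),
                      stringsAsFactors = FALSE)
  if (length(utr) == 1L && is.character(utr) && !is.na(utr) && !nzchar(utr)) {
    return(empty)
  }
  useq <- normalize_rna(utr, what = "UTR")
  patterns <- site_patterns(mirna)[allowed_types]
  subject <- Biostrings::DNAString(chartr("U", "T", useq))
  out <- lapply(names(patterns), function(type) {
    pat <- Biostrings::DNAString(chartr("U", "T", patterns[[type]]))
    if (length(pat) > length(subject)) return(empty)
    m <- Biostrings::matchPattern(pat, subject)
    if (length(m) == 0L) return(empty)
    data.frame(start = Biostrings::start(m) - 1L,
               end = Biostrings::end(m),
               site_type = type,
               seed_binding_seq = mirna$seed_binding,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$start, match(out$site_type, SITE_TYPES)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a UTR collection for seed-match sites
#'
#' @param utrs Named character vector of UTR sequences. Names follow the
#'   `"gene|species"` FASTA header convention used throughout the package.
#' @inheritParams find_seed_sites
#' @return A data.frame with columns `gene`, `species`, `start`, `end`,
#'   `site_type`, `seed_binding_seq`.
#' @export
scan_utr_sites <- function(utrs, mirna,
                           allowed_types = c("8mer", "7mer-m8", "7mer-A1")) {
  if (is.null(names(utrs)) || any(!nzchar(names(utrs)))) {
    stop("`utrs` must be a named vector with 'gene|species' names", call. = FALSE)
  }
  ids <- parse_utr_headers(names(utrs))
  out <- lapply(seq_along(utrs), function(i) {
    s <- find_seed_sites(utrs[[i]], mirna, allowed_types)
    if (nrow(s) == 0L) return(NULL)
    cbind(gene = ids$gene[i], species = ids$species[i], s,
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene = character(), species = character(),
                      start = integer(), end = integer(),
                      site_type = character(), seed_binding_seq = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

## Split "gene|species" headers; errors on malformed or duplicated headers.
parse_utr_headers <- function(headers) {
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    stop("malformed UTR header(s), expected 'gene|species': ",
         paste(headers[bad], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(headers)) {
    stop("duplicated UTR header(s): ",
         paste(unique(headers[duplicated(headers)]), collapse = ", "),
         call. = FALSE)
  }
  data.frame(gene = vapply(parts, `[`, "", 1L),
             species = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Intersect site-bearing genes with a pathway gene list
#'
#' A gene is a predicted target in a species iff it carries at least one
#' candidate site in that species' UTR and belongs to the pathway gene list.
#'
#' @param sites Site table from [scan_utr_sites()] (columns `gene`, `species`).
#' @param pathway_genes Character vector of pathway gene identifiers (same
#'   namespace as the site table's `gene` column).
#' @return Named list (one element per species present in `sites`) of sorted
#'   predicted-target gene vectors.
#' @export
predict_pathway_targets <- function(sites, pathway_genes) {
  stopifnot(is.data.frame(sites), all(c("gene", "species") %in% names(sites)))
  species <- sort(unique(sites$species))
  out <- lapply(species, function(sp) {
    sort(intersect(unique(sites$gene[sites$species == sp]), pathway_genes))
  })
  names(out) <- species
  out
}

#' Introduce point mutations into a site's seed-binding sequence
#'
#' Mutates `n_mutations` distinct positions, all inside the 7-nt seed-binding
#' subsequence of the given site, each to a different randomly chosen base.
#' For any `n_mutations >= 1` the exact-match site of the original type is
#' destroyed at that locus (rescanning will not find it).
#'
#' @param utr UTR sequence (character).
#' @param site One site: a one-row data.frame or list with `start`, `end`,
#'   `site_type` as returned by [find_seed_sites()].
#' @param n_mutations Number of point mutations, 0-7 (default 3, the number
#'   used for seed-mutant reporter constructs).
#' @param rng_seed Optional integer seed for reproducible mutation choice.
#' @return The mutated UTR (RNA alphabet).
#' @export
mutate_seed_binding <- function(utr, site, n_mutations = 3L, rng_seed = NULL) {
  useq <- normalize_rna(utr, what = "UTR")
  start <- as.integer(site$start); end <- as.integer(site$end)
  type <- as.character(site$site_type)
  if (is.na(start) || is.na(end) || start < 0L || end > nchar(useq) || start >= end) {
    stop("site [", start, ",", end, ") out of bounds for UTR of length ",
         nchar(useq), call. = FALSE)
  }
  if (!type %in% SITE_TYPES) stop("unknown site_type: ", type, call. = FALSE)
  n_mutations <- as.integer(n_mutations)
  if (n_mutations < 0L || n_mutations > 7L) {
    stop("n_mutations must be between 0 and 7", call. = FALSE)
  }
  if (n_mutations == 0L) return(useq)
  ## 0-based window holding the 7-nt seed-binding subsequence of this site
  window <- switch(type,
    "7mer-m8"   = c(start, start + 7L),
    "8mer"      = c(start, start + 7L),
    "7mer-A1"   = c(start, start + 7L),
    "perfect23" = c(end - 8L, end - 1L)
  )
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  pos <- sample(seq.int(window[1] + 1L, window[2]), n_mutations)  # 1-based
  bases <- c("A", "C", "G", "U")
  chars <- strsplit(useq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Percent identity of two site sequences under global alignment
#'
#' Needleman-Wunsch end-to-end alignment under simple match/mismatch/linear
#' gap scores; identity is the number of matched columns over all alignment
#' columns (gaps included), times 100.
#'
#' @param a,b Site sequences (character, DNA or RNA). An empty sequence is
#'   defined as 0% identity and raises a warning.
#' @param match,mismatch,gap Alignment scores (defaults 1, -1, -2; the gap
#'   score is linear per gap position).
#' @return Identity percentage between 0 and 100.
#' @examples
#' site_percent_identity("ACGU", "ACGA")  # 75
#' @export
site_percent_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (!nzchar(a) || !nzchar(b)) {
    warning("empty site sequence; identity defined as 0%")
    return(0)
  }
  da <- chartr("U", "T", normalize_rna(a, "site sequence"))
  db <- chartr("U", "T", normalize_rna(b, "site sequence"))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(da), Biostrings::DNAString(db),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = abs(gap)
  )
  columns <- nchar(as.character(Biostrings::pattern(aln)))
  100 * Biostrings::nmatch(aln) / columns
}

#' Seed-binding conservation between two sites
#'
#' @param site_a,site_b Either a site (one-row data.frame or list carrying
#'   `seed_binding_seq`), a bare 7-nt seed-binding string, or `NULL`/`NA`
#'   when no site exists in that species.
#' @return List with `both_present` (flag) and `seed_mismatches` (Hamming
#'   distance of the two 7-mers; `NA` unless both sites are present).
#' @export
seed_conservation <- function(site_a, site_b) {
  sa <- extract_seed_binding(site_a)
  sb <- extract_seed_binding(site_b)
  if (is.null(sa) || is.null(sb)) {
    return(list(both_present = FALSE, seed_mismatches = NA_integer_))
  }
  if (nchar(sa) != 7L || nchar(sb) != 7L) {
    stop("seed-binding sequences must be 7 nt", call. = FALSE)
  }
  mm <- sum(strsplit(sa, "")[[1]] != strsplit(sb, "")[[1]])
  list(both_present = TRUE, seed_mismatches = as.integer(mm))
}

extract_seed_binding <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) {
    if (nrow(x) == 0L) return(NULL)
    x <- x$seed_binding_seq[1L]
  } else if (is.list(x)) {
    x <- x$seed_binding_seq
  }
  if (length(x) != 1L || is.na(x)) return(NULL)
  normalize_rna(as.character(x), "seed-binding sequence")
}

#' Read / write UTR FASTA files
#'
#' Headers follow the `"gene|species"` convention; duplicated headers are an
#' error on read.
#'
#' @param path File path.
#' @return `read_utr_fasta()`: named character vector of sequences.
#' @export
read_utr_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  utrs <- toupper(as.character(set))
  parse_utr_headers(names(utrs))  # validates structure and uniqueness
  utrs
}

#' @rdname read_utr_fasta
#' @param utrs Named character vector of UTR sequences.
#' @export
write_utr_fasta <- function(utrs, path) {
  set <- Biostrings::BStringSet(utrs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
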
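#' Mature miRNA sequence with seed accessors
#'
#' Wraps a mature miRNA sequence (5'->3') and precomputes the seed
#' (positions 2-8) and the 7-nt seed-binding sequence, i.e. the reverse
#' complement of the seed as it appears on the target 3'UTR sense strand.
#'
#' @param name miRNA identifier, e.g. `"miR-125b"`.
#' @param sequence Mature sequence, RNA or DNA alphabet; `T` and `U` are
#'   treated as equivalent and the sequence is normalized to RNA. Length
#'   must be 19-25 nt.
#' @return An object of class `"mirna_sequence"`: a list with elements
#'   `name`, `sequence` (RNA, 5'->3'), `seed` (positions 2-8) and
#'   `seed_binding` (reverse complement of the seed, RNA, 5'->3').
#' @examples
#' mir <- mirna_sequence("miR-125b", "UCCCUGAGACCCUAACUUGUGA")
#' mir$seed
#' mir$seed_binding
#' @export
mirna_sequence <- function(name, sequence) {
  seq <- normalize_rna(sequence, what = "miRNA sequence")
  n <- nchar(seq)
  if (n < 19L || n > 25L) {
    stop("miRNA sequence must be 19-25 nt, got ", n, " nt", call. = FALSE)
  }
  seed <- substr(seq, 2L, 8L)
  structure(
    list(
      name = as.character(name),
      sequence = seq,
      seed = seed,
      seed_binding = reverse_complement_rna(seed)
    ),
    class = "mirna_sequence"
  )
}

#' @export
print.mirna_sequence <- function(x, ...) {
  cat("<mirna_sequence> ", x$name, "\n", sep = "")
  cat("  sequence:     5'-", x$sequence, "-3' (", nchar(x$sequence), " nt)\n", sep = "")
  cat("  seed (2-8):   ", x$seed, "\n", sep = "")
  cat("  seed-binding: ", x$seed_binding, "\n", sep = "")
  invisible(x)
}

## Normalize a nucleotide string to the RNA alphabet (uppercase, T -> U).
## Errors on empty input or characters outside {A,C,G,U,T}.
normalize_rna <- function(x, what = "sequence") {
  if (length(x) != 1L || is.na(x) || !is.character(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  if (!nzchar(x)) stop(what, " is empty", call. = FALSE)
  seq <- chartr("t", "u", toupper(x))
  seq <- chartr("T", "U", seq)
  bad <- gsub("[ACGU]", "", seq)
  if (nzchar(bad)) {
    stop(what, " contains invalid characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "),
         call. = FALSE)
  }
  seq
}

## Reverse complement in the RNA alphabet, returned 5'->3'.
reverse_complement_rna <- function(x) {
  comp <- chartr("ACGU", "UGCA", x)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}
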
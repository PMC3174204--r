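#' Packaged p53-network validation fixture
#'
#' The per-assay positive gene lists for the miR-125b screen of the p53
#' network in human, mouse and zebrafish, encoded as an assay-call table:
#' 22/13/14 screen passers per species, pull-down positives (13 human,
#' 11 mouse, 8 zebrafish), and luciferase positives (10 human, 9 mouse,
#' 7 zebrafish, including zebrafish Ccnc, which passed the screen and the
#' reporter assay but not the pull-down). Screen passers that are not named
#' individually in the source are encoded as screen-pass-only placeholder
#' rows (`Unnamed_*`) so per-species totals are preserved. Species-specific
#' symbols (e.g. mouse `Trp53`, zebrafish `tp53`) are resolved through the
#' bundled orthology table; the bundled annotation table classifies the 20
#' validated genes as apoptosis or cell-cycle regulators.
#'
#' The bundled cross-species site table (`sites`) is a synthetic stand-in:
#' the source shows the Ppp1ca/Prkra/Tp53 binding-site alignments only as a
#' figure, so these sequences were constructed to reproduce the stated
#' identity and seed-conservation relationships (Ppp1ca seed identical in
#' all three species; Tp53 mouse seed carrying 2 point mutations; Prkra
#' seed absent in zebrafish) and are not genomic sequence.
#'
#' @return List with `calls` (species, symbol, assay, result), `orthology`,
#'   `annotations`, and `sites` (synthetic site alignment table).
#' @examples
#' fx <- p53_fixture()
#' summary(validate_targets(fx$calls, fx$orthology))
#' @export
p53_fixture <- function() {
  path <- function(f) system.file("extdata", f, package = "mirvalid",
                                  mustWork = TRUE)
  list(
    calls = utils::read.delim(path("p53_assay_calls.tsv"),
                              stringsAsFactors = FALSE),
    orthology = utils::read.delim(path("p53_orthology.tsv"),
                                  stringsAsFactors = FALSE),
    annotations = utils::read.delim(path("p53_gene_classes.tsv"),
                                    stringsAsFactors = FALSE),
    sites = utils::read.delim(path("synthetic_fig_sites.tsv"),
                              stringsAsFactors = FALSE)
  )
}
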
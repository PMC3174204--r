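simple_orth <- function(df) {
  o <- unique(df[c("species", "symbol")])
  o$canonical <- o$symbol
  o
}

test_that("evidence matrix fills untested cells and validates its inputs", {
  empty <- data.frame(species = character(), symbol = character(),
                      assay = character(), result = character())
  orth <- data.frame(species = "human", symbol = "A", canonical = "A")
  expect_equal(nrow(build_evidence_matrix(empty, orth)), 0L)

  calls <- data.frame(species = "human", symbol = "A",
                      assay = c("screen", "pulldown"), result = "pass")
  mat <- build_evidence_matrix(calls, orth)
  expect_equal(mat$screen, "pass")
  expect_equal(mat$pulldown, "pass")
  expect_equal(mat$luciferase, "not_tested")

  # unmapped symbols are an error naming the offender
  calls2 <- rbind(calls, data.frame(species = "mouse", symbol = "B",
                                    assay = "screen", result = "pass"))
  expect_error(build_evidence_matrix(calls2, orth), "mouse:B")
  # conflicting duplicates are an error; agreeing duplicates collapse
  expect_error(build_evidence_matrix(
    rbind(calls, data.frame(species = "human", symbol = "A",
                            assay = "screen", result = "fail")), orth),
    "conflicting")
  expect_equal(nrow(build_evidence_matrix(rbind(calls, calls[1, ]), orth)), 1L)
  # pull-down without a screen pass violates the workflow
  expect_error(build_evidence_matrix(
    data.frame(species = "human", symbol = "A", assay = "pulldown",
               result = "pass"), orth),
    "workflow")
})

test_that("tier assignment follows the pass-count rules with cross-species pink", {
  calls <- rbind(
    data.frame(species = "human", symbol = "G1",
               assay = c("screen", "pulldown", "luciferase"), result = "pass"),
    data.frame(species = "mouse", symbol = "G1", assay = "screen",
               result = "fail"),
    data.frame(species = "human", symbol = "G2",
               assay = c("screen", "pulldown"), result = c("pass", "pass")),
    data.frame(species = "human", symbol = "G3", assay = "screen",
               result = "pass"),
    data.frame(species = "mouse", symbol = "G4", assay = "screen",
               result = "fail")
  )
  tiers <- assign_tier(build_evidence_matrix(calls, simple_orth(calls)))
  tier_of <- function(g, sp) tiers$tier[tiers$canonical == g & tiers$species == sp]
  expect_equal(tier_of("G1", "human"), "red")
  expect_equal(tier_of("G1", "mouse"), "pink")   # 0 passes here, red elsewhere
  expect_equal(tier_of("G2", "human"), "orange")
  expect_equal(tier_of("G3", "human"), "yellow")
  expect_equal(tier_of("G4", "mouse"), "none")   # 0 passes, no rescue
  expect_setequal(validated_target_set(tiers), c("G1", "G2"))
  # max 1 pass everywhere: not retained
  expect_false(any(tiers$retained[tiers$canonical == "G3"]))
})

test_that("retention is monotone under fail-to-pass flips", {
  set.seed(21)
  for (i in 1:10) {
    n <- 6
    calls <- expand.grid(species = c("s1", "s2"),
                         symbol = paste0("g", seq_len(n)),
                         assay = c("screen", "pulldown", "luciferase"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    calls$result <- sample(c("pass", "fail"), nrow(calls), TRUE)
    # keep the workflow invariant: pulldown rows only for screen passers
    key <- paste(calls$species, calls$symbol)
    screen_pass <- key[calls$assay == "screen" & calls$result == "pass"]
    calls <- calls[calls$assay != "pulldown" | key %in% screen_pass, ]
    orth <- simple_orth(calls)
    base <- assign_tier(build_evidence_matrix(calls, orth))
    retained0 <- validated_target_set(base)
    # flip one random fail to pass (not creating a workflow violation)
    flippable <- which(calls$result == "fail" & calls$assay != "screen")
    if (!length(flippable)) next
    j <- sample(flippable, 1)
    calls$result[j] <- "pass"
    retained1 <- validated_target_set(assign_tier(build_evidence_matrix(calls, orth)))
    expect_true(all(retained0 %in% retained1))
  }
})

test_that("cross-species overlap computes Jaccard indices and intersections", {
  calls <- rbind(
    expand.grid(species = c("a", "b"), symbol = c("X", "Y"),
                assay = c("screen", "pulldown"), KEEP.OUT.ATTRS = FALSE,
                stringsAsFactors = FALSE),
    data.frame(species = "a", symbol = "Z", assay = c("screen", "pulldown"),
               stringsAsFactors = FALSE)
  )
  calls$result <- "pass"
  tiers <- assign_tier(build_evidence_matrix(calls, simple_orth(calls)))
  ov <- cross_species_overlap(tiers)
  expect_equal(ov$per_species$a, c("X", "Y", "Z"))
  expect_equal(ov$per_species$b, c("X", "Y"))
  expect_equal(ov$jaccard["a", "b"], 2 / 3)
  expect_equal(ov$intersection, c("X", "Y"))
  single <- tiers[tiers$species == "a", ]
  class(single) <- class(tiers)
  expect_error(cross_species_overlap(single), "two species")
})

test_that("fixture validation is invariant to call row order", {
  fx <- p53_fixture()
  base <- validate_targets(fx$calls, fx$orthology)
  set.seed(31)
  shuffled <- validate_targets(fx$calls[sample(nrow(fx$calls)), ],
                               fx$orthology)
  expect_identical(base$validated, shuffled$validated)
  expect_identical(base$tiers, shuffled$tiers)
})

test_that("orthology collapsing unifies species-specific symbols", {
  fx <- p53_fixture()
  tv <- validate_targets(fx$calls, fx$orthology)
  # mouse Trp53 and zebrafish tp53 collapse onto canonical Tp53
  tp53 <- tv$tiers[tv$tiers$canonical == "Tp53", ]
  expect_setequal(tp53$species, c("human", "mouse", "zebrafish"))
  expect_equal(tp53$tier[tp53$species == "mouse"], "pink")
  summary_obj <- summary(tv)
  expect_s3_class(summary_obj, "summary.target_validation")
})
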
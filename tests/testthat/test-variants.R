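ctx <- egfr_reference()

test_that("descriptor parsing handles delta, HGVS-like and substitution forms", {
  cases <- list(
    # descriptor, start, end, deleted, inserted, net
    list("ΔE746-A750", 746L, 750L, 5L, "", 5L),
    list("E746_A750del", 746L, 750L, 5L, "", 5L),
    list("delE746-A750", 746L, 750L, 5L, "", 5L),
    list("ΔL747-A750InsP", 747L, 750L, 4L, "P", 3L),
    list("L747_A750delinsP", 747L, 750L, 4L, "P", 3L),
    list("E746_S752delinsV", 746L, 752L, 7L, "V", 6L),
    list("ΔE746-L747InsIP", 746L, 747L, 2L, "IP", 0L),
    list("ΔL747-T751InsP", 747L, 751L, 5L, "P", 4L),
    list("Δ E746 – A750", 746L, 750L, 5L, "", 5L)  # whitespace + en dash
  )
  for (cs in cases) {
    v <- parse_variant(cs[[1]], ctx)
    expect_identical(v$deletion_start, cs[[2]], label = cs[[1]])
    expect_identical(v$deletion_end, cs[[3]], label = cs[[1]])
    expect_identical(v$deleted_count, cs[[4]], label = cs[[1]])
    expect_identical(v$inserted_sequence, cs[[5]], label = cs[[1]])
    expect_identical(v$net_loop_shortening, cs[[6]], label = cs[[1]])
    expect_null(v$substitution)
  }
  s <- parse_variant("L747P", ctx)
  expect_identical(s$substitution,
                   list(position = 747L, ref_aa = "L", alt_aa = "P"))
  expect_identical(s$deleted_count, 0L)
  expect_identical(s$net_loop_shortening, 0L)
})

test_that("parsing rejects malformed, mismatched and out-of-range descriptors", {
  expect_error(parse_variant("not-a-variant", ctx), "unrecognised token")
  expect_error(parse_variant("", ctx), "non-empty")
  expect_error(parse_variant("ΔK746-A750", ctx), "reference mismatch")
  expect_error(parse_variant("A750_E746del", ctx), "precedes")
  expect_error(parse_variant("ΔE900-A905", ctx), "outside the reference")
  # deletion crossing the loop boundary warns but still parses
  expect_warning(v <- parse_variant("ΔE758-L760", egfr_reference()),
                 "beyond the configured loop window")
  expect_error(parse_variant("ΔA763-Y764", ctx), "entirely outside")
})

test_that("precursor/mature numbering conversion round-trips with offset 24", {
  expect_identical(convert_numbering(746, "precursor_to_mature"), 722L)
  expect_identical(
    convert_numbering(convert_numbering(25, "precursor_to_mature"),
                      "mature_to_precursor"), 25L)
  expect_error(convert_numbering(1, "precursor_to_mature"), "not positive")
  expect_error(convert_numbering(0), "positive")
})

test_that("apply_variant splices deletions, insertions and substitutions", {
  ref <- ctx$sequence
  # three-residue deletion removes exactly LRE
  out <- apply_variant(parse_variant("ΔL747-E749", ctx), ctx)
  expect_identical(out, sub("LRE", "", ref, fixed = TRUE))
  # indel: LREA replaced by P, 3 shorter than reference
  out2 <- apply_variant(parse_variant("ΔL747-A750InsP", ctx), ctx)
  expect_identical(out2, sub("LREA", "P", ref, fixed = TRUE))
  expect_identical(nchar(out2), nchar(ref) - 3L)
  # substitution replaces one letter in place
  out3 <- apply_variant(parse_variant("L747P", ctx), ctx)
  expect_identical(nchar(out3), nchar(ref))
  expect_identical(substr(out3, 747 - ctx$seq_start + 1, 747 - ctx$seq_start + 1), "P")
})

test_that("output length always equals reference length minus net shortening", {
  descriptors <- c(cohort_variant_counts("registry")$descriptor,
                   cohort_variant_counts("institutional")$descriptor,
                   "L747P", "ΔL747-E749")
  for (d in unique(descriptors)) {
    v <- parse_variant(d, ctx)
    expect_identical(nchar(apply_variant(v, ctx)),
                     nchar(ctx$sequence) - v$net_loop_shortening,
                     label = d)
  }
})

test_that("profile rule assigns 1 iff net shortening <= 3, with proline flag", {
  p <- classify_profile(parse_variant("ΔE746-A750", ctx))
  expect_identical(p$profile, 2L)
  expect_identical(p$net_loop_shortening, 5L)
  # boundary pair differing by a single extra deleted residue
  expect_identical(classify_profile(parse_variant("ΔL747-A750InsP", ctx))$profile, 1L)
  expect_identical(classify_profile(parse_variant("ΔL747-T751InsP", ctx))$profile, 2L)
  # proline substitution: profile 1 but activation predicted
  lp <- classify_profile(parse_variant("L747P", ctx))
  expect_identical(lp$profile, 1L)
  expect_true(lp$proline_introduced)
  expect_true(lp$activation_predicted)
  # short deletion without proline: profile 1, no activation predicted
  e749 <- classify_profile(parse_variant("ΔL747-E749", ctx))
  expect_identical(e749$profile, 1L)
  expect_false(e749$activation_predicted)
})

test_that("every published cohort descriptor classifies to its stated profile", {
  for (cohort in c("registry", "institutional")) {
    tab <- cohort_variant_counts(cohort)
    got <- classify_variants(tab$descriptor, ctx)
    expect_identical(got$profile, tab$profile, label = cohort)
  }
  # published kinetic table groupings (excluding exon 21 controls)
  kin <- egfr_kinetic_table()
  kin <- kin[kin$group %in% c("profile 1", "profile 2"), ]
  got <- classify_variants(kin$variant, ctx)
  expect_identical(paste("profile", got$profile), kin$group)
})

test_that("canonical serialisation round-trips through the parser", {
  for (d in c("ΔE746-A750", "ΔL747-A750InsP", "L747P", "E746_S752delinsV",
              "ΔT751-I759InsN")) {
    v <- parse_variant(d, ctx)
    canon <- format_variant(v, ctx)
    v2 <- parse_variant(canon, ctx)
    expect_identical(format_variant(v2, ctx), canon, label = d)
    expect_identical(v2$net_loop_shortening, v$net_loop_shortening, label = d)
  }
})

test_that("net insertions are outside the rule's domain", {
  # hypothetical exon-20-like net insertion built by hand
  v <- parse_variant("ΔL747-E749", ctx)
  v$inserted_sequence <- "GGGG"
  v$net_loop_shortening <- v$deleted_count - 4L
  expect_error(classify_profile(v), "net insertion")
})
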
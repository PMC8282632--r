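test_that("probability matrices count residues with the declared denominator", {
  aln <- mk_aln(c("AC", "AG", "W-", "A-"), c("s1", "s2", "s3", "s4"))
  lab <- label_table(aln$ids, c("binder", "binder", "nonbinder", "nonbinder"),
                    alignment = aln)

  pb <- build_probability_matrix(aln, lab, "BINDER")
  expect_equal(unname(pb$values[1, "A"]), 1.0)
  expect_equal(unname(pb$values[2, "C"]), 0.5)
  expect_equal(unname(pb$values[2, "G"]), 0.5)
  expect_equal(sum(pb$values[1, ]), 1)

  # one-sequence group: one-hot column, all-zero where gapped
  pn <- build_probability_matrix(
    aln, label_table(c("s1", "s3"), c("binder", "nonbinder"), alignment = aln),
    "NONBINDER")
  expect_equal(unname(pn$values[1, "W"]), 1.0)
  expect_equal(unname(pn$values[2, ]), rep(0, 20))
  expect_equal(pn$column_support, c(1L, 0L))

  # non-gap denominator: {"W-","A-"} has support 0 at column 2;
  # {"A-","AC"} style case via the nonbinder group of the 4-row alignment
  pnb <- build_probability_matrix(aln, lab, "NONBINDER")
  expect_equal(pnb$values[2, ], setNames(rep(0, 20), colnames(pnb$values)),
               ignore_attr = TRUE)

  # support-1 column under both denominators: group {"A-","AC"}
  p_ng <- build_probability_matrix(mk_aln(c("A-", "AC", "GG"), c("a", "b", "c")),
    label_table(c("a", "b", "c"), c("binder", "binder", "nonbinder"),
                alignment = mk_aln(c("A-", "AC", "GG"), c("a", "b", "c"))),
    "BINDER")
  expect_equal(unname(p_ng$values[2, "C"]), 1.0)
  p_gs <- build_probability_matrix(mk_aln(c("A-", "AC", "GG"), c("a", "b", "c")),
    label_table(c("a", "b", "c"), c("binder", "binder", "nonbinder"),
                alignment = mk_aln(c("A-", "AC", "GG"), c("a", "b", "c"))),
    "BINDER", denominator = "group-size")
  expect_equal(unname(p_gs$values[2, "C"]), 0.5)

  # frequency definition: every entry is counts / denominator exactly
  expect_equal(pb$values * ifelse(pb$denom == 0, 1, pb$denom), pb$counts,
               ignore_attr = TRUE)

  expect_error(build_probability_matrix(
    mk_aln("AC", "q1"),
    structure(data.frame(id = "q1", label = "BINDER"),
              class = c("rfc_labels", "data.frame")), "NONBINDER"),
    "empty")
})

test_that("RFC entries are log ratios under the declared base and zero policy", {
  aln <- mk_aln(c("AA", "AC", "AA", "CA"), c("b1", "b2", "n1", "n2"))
  lab <- mk_labels(aln, 2)
  pb <- build_probability_matrix(aln, lab, "BINDER")
  pnb <- build_probability_matrix(aln, lab, "NONBINDER")

  rfc <- build_rfc_matrix(pb, pnb)
  # col 1: P^B(A)=1, P^NB(A)=0.5 -> ln 2
  expect_equal(unname(rfc$values[1, "A"]), log(2))
  # zero-out: P^B(C)=0 at col 1 although P^NB(C)=0.5 -> 0
  expect_equal(unname(rfc$values[1, "C"]), 0)

  # identical groups give the all-zero matrix
  aln2 <- mk_aln(c("AC", "AC"), c("x", "y"))
  lab2 <- mk_labels(aln2, 1)
  z <- build_rfc(aln2, lab2)
  expect_true(all(z$values == 0))

  # pseudocount keeps everything finite
  ps <- build_rfc_matrix(pb, pnb, zero_policy = "pseudocount")
  expect_true(all(is.finite(ps$values)))

  # base-10 scores are natural-log scores divided by ln 10
  r10 <- build_rfc_matrix(pb, pnb, log_base = "10")
  expect_equal(r10$values, rfc$values / log(10))

  expect_error(build_rfc_matrix(pnb, pb), "BINDER")
  short <- mk_aln(c("A", "C"), c("u", "v"))
  labs <- mk_labels(short, 1)
  expect_error(build_rfc_matrix(build_probability_matrix(short, labs, "BINDER"),
                                pnb), "shapes")
})

test_that("scoring sums matching entries and gaps contribute zero", {
  rfc <- build_rfc(mk_aln(c("AC", "GC"), c("b", "n")), mk_labels(mk_aln(c("AC", "GC"), c("b", "n")), 1))
  # hand-built matrix for exact sums
  v <- matrix(0, 2, 20, dimnames = list(NULL, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  v[1, "A"] <- 0.7; v[2, "C"] <- -0.2
  rfc$values <- v
  expect_equal(score_sequence(rfc, "AC"), 0.5)
  expect_equal(score_sequence(rfc, "--"), 0)
  expect_equal(score_sequence(rfc, "A-"), 0.7)
  expect_equal(score_sequence(rfc, "AC", columns = 2L), -0.2)
  rfc$values[] <- 0
  expect_equal(score_sequence(rfc, "WY"), 0)
  expect_error(score_sequence(rfc, "ACD"), "does not match")
  expect_error(score_sequence(rfc, "AC", columns = 3L), "out of range")
})

test_that("region components sum to the full score for any partition", {
  set.seed(42)
  for (i in 1:20) {
    inst <- random_instance(n = 6, L = 10)
    rfc <- build_rfc(inst$alignment, inst$labels)
    cut <- sort(sample(2:9, 2))
    rm_ <- region_map(c("r1", "r2"), c(1, cut[1]), c(cut[1] - 1, cut[2] - 1),
                      L = 10)
    sc <- score_all(rfc, inst$alignment, regions = rm_)   # + complement
    comp <- as.matrix(sc[, attr(sc, "region_names")])
    expect_equal(unname(rowSums(comp)), sc$s_rfc, tolerance = 1e-9)
  }
})

test_that("swapping the label groups negates every score under zero-out", {
  set.seed(7)
  for (i in 1:15) {
    inst <- random_instance(n = 6, L = 8)
    flipped <- label_table(inst$labels$id,
                           ifelse(inst$labels$label == "BINDER",
                                  "nonbinder", "binder"),
                           alignment = inst$alignment)
    r1 <- build_rfc(inst$alignment, inst$labels)
    r2 <- build_rfc(inst$alignment, flipped)
    expect_equal(r2$values, -r1$values)
    expect_equal(score_all(r2, inst$alignment)$s_rfc,
                 -score_all(r1, inst$alignment)$s_rfc)
  }
})

test_that("a naive per-residue loop reproduces the vectorized scorer exactly", {
  naive_score <- function(rfc, row) {
    ch <- strsplit(row, "")[[1]]
    aa <- colnames(rfc$values)
    contrib <- numeric(length(ch))
    for (j in seq_along(ch))
      if (ch[j] != "-") contrib[j] <- rfc$values[j, match(ch[j], aa)]
    sum(contrib)
  }
  set.seed(99)
  for (i in 1:100) {
    inst <- random_instance(n = 5, L = sample(3:12, 1))
    rfc <- build_rfc(inst$alignment, inst$labels,
                     zero_policy = sample(c("zero-out", "pseudocount"), 1))
    got <- score_all(rfc, inst$alignment)$s_rfc
    want <- vapply(inst$alignment$rows, naive_score, numeric(1),
                   rfc = rfc, USE.NAMES = FALSE)
    expect_identical(got, want)
  }
})

test_that("region fractions normalize components and flag all-zero rows", {
  # hand matrix so the components are (2, 1, 1)
  rfc <- build_rfc(mk_aln(c("AAAA", "CCCC"), c("b", "n")),
                   mk_labels(mk_aln(c("AAAA", "CCCC"), c("b", "n")), 1))
  v <- matrix(0, 4, 20, dimnames = list(NULL, colnames(rfc$values)))
  v[1, "A"] <- 2; v[2, "A"] <- 1; v[3, "A"] <- 1
  rfc$values <- v
  rm_ <- region_map(c("r1", "r2", "r3"), c(1, 2, 3), c(1, 2, 3), L = 4)
  sc <- score_all(rfc, mk_aln(c("AAA-", "----"), c("q1", "q2")), regions = rm_)
  fr <- region_fractions(sc)
  expect_equal(unlist(fr[1, c("r1", "r2", "r3")], use.names = FALSE),
               c(0.5, 0.25, 0.25))
  expect_true(all(is.na(fr[2, -1])))   # all-zero components -> missing
  # single region spanning everything -> fraction 1
  sc2 <- score_all(rfc, mk_aln("AAAA", "q"), regions = region_map("all", 1, 4, L = 4),
                   complement = FALSE)
  expect_equal(region_fractions(sc2)$all, 1)
  expect_error(region_fractions(score_all(rfc, mk_aln("AAAA", "q"))),
               "no region components")
})

test_that("position contributions are mean squared entries with index tie-breaks", {
  rfc <- build_rfc(mk_aln(c("AAA", "CCC"), c("b", "n")),
                   mk_labels(mk_aln(c("AAA", "CCC"), c("b", "n")), 1))
  v <- matrix(0, 3, 20, dimnames = list(NULL, colnames(rfc$values)))
  rfc$values <- v
  co <- position_contributions(rfc)
  expect_equal(co$contribution, rep(0, 3))
  expect_equal(co$ranking, 1:3)              # ties -> lower index first

  rfc$values[2, "W"] <- -1.5
  co <- position_contributions(rfc)
  expect_equal(co$contribution[2], 1.5^2 / 20)
  expect_equal(co$ranking[1], 2L)
  expect_true(all(co$contribution >= 0))

  # increasing a column's divergence never decreases its contribution
  prev <- -Inf
  for (d in c(0.1, 0.5, 1, 2, 4)) {
    rfc$values[3, "A"] <- d; rfc$values[3, "C"] <- -d
    cj <- position_contributions(rfc)$contribution[3]
    expect_gte(cj, prev)
    prev <- cj
  }
})

test_that("RFC matrix TSV round trip preserves values and policy metadata", {
  inst <- random_instance(n = 6, L = 7)
  rfc <- build_rfc(inst$alignment, inst$labels, zero_policy = "pseudocount",
                   log_base = "10")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_rfc_matrix(rfc, f)
  back <- read_rfc_matrix(f)
  expect_equal(back$values, rfc$values, tolerance = 1e-12)
  expect_equal(back$log_base, "10")
  expect_equal(back$zero_policy, "pseudocount")
  expect_equal(score_all(back, inst$alignment)$s_rfc,
               score_all(rfc, inst$alignment)$s_rfc, tolerance = 1e-10)
})
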
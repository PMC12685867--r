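test_that("alphabet and schema anchors resolve as named", {
  expect_identical(alphabetOrder()[c(5, 11, 13)], c("C", "L", "M"))
  s <- featureSchemaTable()
  expect_identical(nrow(s), 1103L)
  expect_false(anyDuplicated(s$name) > 0)
  expect_identical(
    as.integer(table(factor(s$family, levels = unique(s$family)))),
    c(20L, 400L, 30L, 40L, 21L, 21L, 105L, 6L, 20L, 40L, 400L))
  # aac_5 is the cysteine composition
  expect_equal(unname(extractAAC("CCCCG")["aac_5"]), 0.8)
  # dist_93 is the 50% occurrence quantile of solvent-accessibility group 1
  # (buried residues): in "ARRR", the only buried residue is A at position 1
  expect_equal(unname(extractCTD("ARRR")["dist_93"]), 100 * 1 / 4)
})

test_that("amino-acid composition matches hand counts", {
  expect_equal(unname(extractAAC("AAAA")), c(1, rep(0, 19)))
  expect_equal(unname(extractAAC("ARND")), c(rep(0.25, 4), rep(0, 16)))
  v <- extractAAC("CCCCG")
  expect_equal(unname(v[c(5, 8)]), c(0.8, 0.2))
  expect_equal(sum(v), 1)
})

test_that("dipeptide composition matches pair enumeration", {
  v <- extractDC("AAAAA")
  expect_equal(unname(v["dipep_1"]), 1)
  expect_equal(sum(v), 1)
  v <- extractDC("ACAC")  # pairs AC, CA, AC over 3 slots
  expect_equal(unname(v["dipep_5"]), 2 / 3)            # (A,C): (1-1)*20+5
  expect_equal(unname(v["dipep_81"]), 1 / 3)           # (C,A): (5-1)*20+1
  expect_length(extractDC(randomSeq(25, seed = 1)), 400)
  expect_error(extractDC("A"), "too short")
})

test_that("brute-force oracle reproduces AAC and DC on short sequences", {
  aacOracle <- function(x) {
    ch <- strsplit(x, "")[[1]]
    vapply(alphabetOrder(), function(a) sum(ch == a), numeric(1)) / nchar(x)
  }
  dcOracle <- function(x) {
    ch <- strsplit(x, "")[[1]]
    out <- numeric(400)
    for (i in seq_len(nchar(x) - 1))
      for (a in 1:20) for (b in 1:20)
        if (ch[i] == alphabetOrder()[a] && ch[i + 1] == alphabetOrder()[b])
          out[(a - 1) * 20 + b] <- out[(a - 1) * 20 + b] + 1
    out / (nchar(x) - 1)
  }
  set.seed(42)
  for (rep in 1:5) {
    x <- randomSeq(sample(4:10, 1))
    expect_equal(unname(extractAAC(x)), unname(aacOracle(x)))
    expect_equal(unname(extractDC(x)), dcOracle(x))
  }
})

test_that("pseudo amino-acid composition normalizes and collapses correctly", {
  homo <- strrep("A", 12)
  v <- extractPAAC(homo)
  expect_equal(unname(v[1]), 1)                       # tau = 0 for identical
  expect_equal(unname(v[21:30]), rep(0, 10))
  p0 <- descriptorParams(wPaac = 0)
  x <- randomSeq(35, seed = 7)
  expect_equal(unname(extractPAAC(x, p0)[1:20]), unname(extractAAC(x)))
  v <- extractPAAC(x)
  expect_length(v, 30)
  expect_true(all(v >= 0))
  expect_equal(sum(v), 1, tolerance = 1e-9)
  expect_error(extractPAAC(randomSeq(10)), "must exceed")
})

test_that("amphiphilic pseudo composition alternates scales and normalizes", {
  v <- extractAPAAC(strrep("K", 15))
  expect_equal(unname(v[12]), 1)                      # K is position 12
  expect_equal(unname(v[21:40]), rep(0, 20))
  x <- randomSeq(40, seed = 8)
  expect_equal(unname(extractAPAAC(x, descriptorParams(wApaac = 0))[1:20]),
               unname(extractAAC(x)))
  v <- extractAPAAC(x)
  expect_length(v, 40)
  expect_equal(sum(v), 1, tolerance = 1e-9)
  # odd tail entries use hydrophobicity only: a sequence alternating two
  # residues with equal hydrophilicity has zero even entries at lag 1
  # (T and S differ in hydrophilicity, so use A/H: hydrophilicity both -0.5)
  w <- extractAPAAC(strrep("AH", 8))
  expect_equal(unname(w[22]), 0)                      # hydrophilicity lag 1
  expect_gt(w[21], 0)                                 # hydrophobicity lag 1
})

test_that("CTD features match hand enumeration on the charge property", {
  v <- extractCTD("KKDD")
  # charge is property 5: comp_13..15, tran_13..15, dist_61..75
  expect_equal(unname(v[paste0("comp_", 13:15)]), c(0.5, 0, 0.5))
  expect_equal(unname(v[paste0("tran_", 13:15)]), c(0, 1 / 3, 0))
  expect_equal(unname(v[paste0("dist_", 61:65)]), c(25, 25, 25, 50, 50))
  # homopolymer: exactly one group per property is full, no transitions
  h <- extractCTD(strrep("G", 9))
  comp <- matrix(h[1:21], nrow = 3)
  expect_equal(unname(colSums(comp)), rep(1, 7))
  expect_true(all(colSums(comp == 1) == 1))
  expect_equal(unname(h[22:42]), rep(0, 21))
  # distribution values always lie in [0, 100]
  d <- extractCTD(randomSeq(50, seed = 9))[43:147]
  expect_true(all(d >= 0 & d <= 100))
  # composition sums to 1 per property
  expect_equal(unname(colSums(matrix(extractCTD(randomSeq(30))[1:21], 3))),
               rep(1, 7))
})

test_that("secondary-structure summaries count fractions and runs", {
  expect_equal(unname(extractSS("ARND", ss = "HHHH")), c(1, 0, 0, 1, 0, 0))
  expect_equal(unname(extractSS("ARND", ss = "HECH")),
               c(0.5, 0.25, 0.25, 0.25, 0.25, 0.25))
  expect_length(extractSS(randomSeq(30, seed = 2)), 6)
  expect_error(extractSS("ARND", ss = "HH"), "does not match")
  expect_error(extractSS("ARND", ss = "HHGX"), "states")
  # fallback predictor emits valid states of the right length
  st <- predictSSPropensity(randomSeq(25, seed = 3))
  expect_match(st, "^[HEC]{25}$")
})

test_that("sequence-order coupling numbers follow the distance matrix", {
  expect_equal(unname(extractSOCN(strrep("A", 25))), rep(0, 20))
  d <- aaDistanceMatrix()
  expect_equal(unname(extractSOCN("AC", descriptorParams(maxlagSo = 1))),
               d["A", "C"]^2)
  x <- randomSeq(30, seed = 4)
  v <- extractSOCN(x)
  expect_length(v, 20)
  # brute-force oracle at one lag
  ch <- strsplit(x, "")[[1]]
  tau3 <- sum(vapply(1:(30 - 3), function(i) d[ch[i], ch[i + 3]]^2,
                     numeric(1)))
  expect_equal(unname(v[3]), tau3)
  expect_error(extractSOCN(randomSeq(20)), "minimum length 21")
})

test_that("quasi-sequence-order normalizes and collapses to AAC", {
  h <- extractQSO(strrep("W", 30))
  expect_equal(unname(h[18]), 1)                      # W is position 18
  expect_equal(unname(h[21:40]), rep(0, 20))
  x <- randomSeq(28, seed = 6)
  expect_equal(unname(extractQSO(x, descriptorParams(wQso = 0))[1:20]),
               unname(extractAAC(x)))
  v <- extractQSO(x)
  expect_length(v, 40)
  expect_true(all(v >= 0))
  expect_equal(sum(v), 1, tolerance = 1e-9)
})

test_that("PSSM transition features squash and average adjacent products", {
  # all-zero scores: sigma = 0.5 everywhere, every product is 0.25
  v <- extractPSSMTransition("ACD", profile = matrix(0, 3, 20))
  expect_equal(unname(v), rep(0.25, 400))
  # near-one-hot rows: only the (A, C) transition fires
  prof <- matrix(-50, 2, 20); prof[1, 1] <- 50; prof[2, 5] <- 50
  v <- extractPSSMTransition("AC", profile = prof)
  expect_equal(unname(v["pssm_5"]), 1, tolerance = 1e-12)
  expect_equal(sum(v), 1, tolerance = 1e-12)
  expect_length(extractPSSMTransition(randomSeq(25, seed = 1)), 400)
  expect_error(extractPSSMTransition("ACD", profile = matrix(0, 4, 20)),
               "rows")
})

test_that("featurize assembles the 1,103-feature panel deterministically", {
  x <- randomSeq(30, seed = 10)
  fm <- featurize(c(s1 = x, s2 = x, s3 = randomSeq(40)))
  expect_identical(dim(fm), c(3L, 1103L))
  expect_identical(featureSchema(fm)$name, featureSchemaTable()$name)
  v <- featureValues(fm)
  expect_equal(v["s1", ], v["s2", ])                  # identical sequences
  # permuting input order permutes rows but not values
  fm2 <- featurize(c(s3 = randomSeq(40, seed = NULL), s1 = x)[c("s1", "s3")])
  expect_equal(featureValues(fm)["s1", ], featureValues(fm2)["s1", ])
  # family errors carry the sequence id
  expect_error(featurize(c(ok = x, short = "ACDEF")), "short")
  # an explicit profile changes only the pssm block
  prof <- list(s1 = matrix(0, 30, 20))
  fm3 <- featurize(c(s1 = x), profiles = prof)
  expect_equal(featureValues(fm3)[1, 1:703], v["s1", 1:703])
  expect_equal(unname(featureValues(fm3)[1, 704:1103]), rep(0.25, 400))
  expect_identical(fm3@metadata$pssmFallback, character(0))
})
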
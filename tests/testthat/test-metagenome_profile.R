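mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(read_id = r[[1]], subject_id = r[[2]],
               pct_identity = as.numeric(r[[3]]),
               align_len = as.integer(r[[4]]), evalue = as.numeric(r[[5]]),
               bit_score = as.numeric(r[[6]]), stringsAsFactors = FALSE)
  }))
}

test_that("best hit per read maximizes bit score with a deterministic tie-break", {
  fam <- c(pA = "F1", pB = "F2", pC = "F1")
  hits <- mk_hits(list("r1", "pB", 99, 100, 1e-20, 80),
                  list("r1", "pA", 99, 100, 1e-20, 60))
  best <- best_hit_per_read(hits, fam)
  expect_identical(best$subject_id, "pB")

  # identical score and e-value: lexicographically smallest subject wins
  tie <- mk_hits(list("r1", "pB", 99, 100, 1e-20, 80),
                 list("r1", "pA", 99, 100, 1e-20, 80))
  expect_identical(best_hit_per_read(tie, fam)$subject_id, "pA")

  # same score, different e-value: lower e-value wins
  ev <- mk_hits(list("r1", "pA", 99, 100, 1e-10, 80),
                list("r1", "pC", 99, 100, 1e-20, 80))
  expect_identical(best_hit_per_read(ev, fam)$subject_id, "pC")

  # result is invariant to input row order
  expect_identical(best_hit_per_read(tie[2:1, ], fam),
                   best_hit_per_read(tie, fam))

  # unmapped subjects are dropped and counted
  un <- mk_hits(list("r2", "pZ", 99, 100, 1e-20, 90))
  got <- best_hit_per_read(un, fam)
  expect_equal(nrow(got), 0L)
  expect_equal(attr(got, "n_unmapped"), 1L)
})

test_that("presence calling enforces identity and whole-read coverage", {
  fam <- c(pA = "F1", pB = "F2")
  best <- best_hit_per_read(
    mk_hits(list("r1", "pA", 99.5, 100, 1e-20, 80),   # counted
            list("r2", "pA", 98.0, 100, 1e-20, 80),   # identity below 99
            list("r3", "pB", 100, 99, 1e-20, 80),     # shorter than the read
            list("r4", "pB", 99.0, 120, 1e-20, 80)),  # counted (boundary)
    fam)
  counts <- call_presence(best, read_length = 100,
                          family_ids = c("F1", "F2"))
  expect_identical(counts, c(F1 = 1L, F2 = 1L))
  expect_true(all(counts[counts >= 1] >= 1))  # one read suffices for presence
  expect_error(call_presence(best, read_length = NULL), "read_length")
})

test_that("counts match a brute-force per-read tally and ignore duplicate hit rows", {
  set.seed(41)
  fam_ids <- sprintf("F%02d", 1:6)
  subjects <- sprintf("p%02d", 1:18)
  s2f <- setNames(rep(fam_ids, each = 3), subjects)
  for (rep in 1:10) {
    n_reads <- 60
    rows <- lapply(seq_len(n_reads), function(r) {
      k <- sample(3, 1)
      do.call(rbind, lapply(seq_len(k), function(j) {
        data.frame(read_id = sprintf("r%03d", r),
                   subject_id = sample(subjects, 1),
                   pct_identity = round(runif(1, 95, 100), 1),
                   align_len = sample(c(80L, 100L, 110L), 1),
                   evalue = 10^-sample(5:30, 1),
                   bit_score = round(runif(1, 40, 90), 1),
                   stringsAsFactors = FALSE)
      }))
    })
    hits <- do.call(rbind, rows)
    counts <- call_presence(best_hit_per_read(hits, s2f), read_length = 100,
                            family_ids = fam_ids)
    # oracle: explicit loop over reads, best hit by (bits, -evalue, subject)
    oracle <- setNames(integer(length(fam_ids)), fam_ids)
    for (r in unique(hits$read_id)) {
      h <- hits[hits$read_id == r, ]
      h <- h[order(-h$bit_score, h$evalue, h$subject_id), ][1, ]
      if (h$pct_identity >= 99 && h$align_len >= 100) {
        oracle[s2f[[h$subject_id]]] <- oracle[s2f[[h$subject_id]]] + 1L
      }
    }
    expect_identical(counts, oracle)
    # duplicating every hit row must not change counts (best-hit dedup)
    dup <- call_presence(best_hit_per_read(rbind(hits, hits), s2f),
                         read_length = 100, family_ids = fam_ids)
    expect_identical(dup, counts)
  }
})

test_that("rpkg follows count / (mean aa length * 3 / 1000) / genome equivalents", {
  counts <- matrix(c(10L, 0L), 2, 1, dimnames = list(c("F1", "F2"), "s1"))
  got <- rpkg(counts, c(F1 = 250, F2 = 100), c(s1 = 20))
  expect_equal(got["F1", "s1"], 10 / 0.75 / 20, tolerance = 1e-12)
  expect_equal(got["F2", "s1"], 0)

  # doubling genome equivalents halves every value; scaling counts is linear
  set.seed(42)
  counts <- matrix(rpois(12, 5), 3, 4,
                   dimnames = list(paste0("F", 1:3), paste0("s", 1:4)))
  len <- setNames(runif(3, 100, 400), paste0("F", 1:3))
  ge <- setNames(runif(4, 5, 50), paste0("s", 1:4))
  expect_equal(rpkg(counts, len, 2 * ge), rpkg(counts, len, ge) / 2)
  expect_equal(rpkg(2 * counts, len, ge), 2 * rpkg(counts, len, ge))
  expect_error(rpkg(counts, len, ge * 0), "positive")
})

test_that("prevalence is the per-environment presence fraction", {
  presence <- matrix(c(rep(TRUE, 9), FALSE,  rep(FALSE, 10)),
                     nrow = 2, byrow = TRUE,
                     dimnames = list(c("F1", "F2"), sprintf("s%02d", 1:10)))
  env <- setNames(rep("ENV_A", 10), colnames(presence))
  prev <- prevalence(presence, env)
  expect_equal(prev["F1", "ENV_A"], 0.9)
  expect_equal(prev["F2", "ENV_A"], 0.0)

  # two environments with disjoint presence, checked by hand count
  presence2 <- cbind(presence,
                     matrix(c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE),
                            nrow = 2, dimnames = list(NULL, c("t1", "t2", "t3"))))
  env2 <- setNames(c(rep("ENV_A", 10), rep("ENV_B", 3)), colnames(presence2))
  prev2 <- prevalence(presence2, env2)
  expect_equal(prev2["F1", "ENV_B"], 1 / 3)  # hand count: present in t3 only
  expect_equal(prev2["F2", "ENV_B"], 2 / 3)  # present in t1 and t2
  expect_equal(prev2["F1", "ENV_A"], 0.9)
})

test_that("binary presence entropy matches the closed form", {
  expect_equal(presence_entropy(c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(presence_entropy(rep(TRUE, 5)), 0.0)
  p <- 0.25
  expect_equal(presence_entropy(c(TRUE, FALSE, FALSE, FALSE)),
               -p * log2(p) - (1 - p) * log2(1 - p), tolerance = 1e-12)
  expect_equal(presence_entropy(c(TRUE, FALSE, FALSE, FALSE)), 0.811278,
               tolerance = 1e-6)
  m <- rbind(F1 = c(TRUE, FALSE), F2 = c(TRUE, TRUE))
  expect_equal(presence_entropy(m), c(F1 = 1, F2 = 0))
})

test_that("entropy filter retains the top quantile with ties and degenerate cases", {
  e <- setNames((1:8) / 10, sprintf("F%d", 1:8))
  expect_setequal(entropy_filter(e, 0.25), c("F7", "F8"))
  expect_setequal(entropy_filter(setNames(rep(0.5, 6), paste0("F", 1:6)),
                                 0.25), paste0("F", 1:6))
  expect_identical(entropy_filter(c(Fx = 0.3), 0.25), "Fx")
  expect_setequal(entropy_filter(e, 1.0), names(e))
  expect_error(entropy_filter(e, 0), "top_fraction")
  expect_error(entropy_filter(e, 1.5), "top_fraction")
})

test_that("phylum filter thresholds breadth and degenerates at 1", {
  sel <- data.frame(family_id = c("F1", "F2", "F3"), n_phyla = c(2L, 1L, 3L))
  expect_setequal(phylum_filter(sel, 2), c("F1", "F3"))
  expect_setequal(phylum_filter(sel, 1), sel$family_id)
})

test_that("Bray-Curtis matches the closed form and its metric-like properties", {
  expect_equal(bray_curtis(c(1, 2), c(2, 1)), 1 - 4 / 6, tolerance = 1e-12)
  expect_equal(bray_curtis(c(3, 1, 0), c(3, 1, 0)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  set.seed(43)
  for (rep in 1:20) {
    x <- rexp(6); y <- rexp(6)
    expect_equal(bray_curtis(x, y), bray_curtis(y, x))
    expect_true(bray_curtis(x, y) >= 0 && bray_curtis(x, y) <= 1)
    c0 <- runif(1, 0.1, 10)
    expect_equal(bray_curtis(c0 * x, c0 * y), bray_curtis(x, y),
                 tolerance = 1e-12)
  }
})

test_that("the dissimilarity matrix agrees with the pairwise formula", {
  set.seed(44)
  ab <- matrix(rexp(24), 4, 6,
               dimnames = list(paste0("F", 1:4), paste0("s", 1:6)))
  bc <- bc_matrix(ab)
  expect_equal(diag(bc), setNames(rep(0, 6), paste0("s", 1:6)))
  expect_equal(bc, t(bc))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(bc[i, j], bray_curtis(ab[, i], ab[, j]), tolerance = 1e-12)
  }
})

test_that("beta diversity partitions pairs and detects planted separation", {
  # 2 + 2 samples: one within pair per environment, four between pairs
  bc <- matrix(0.5, 4, 4,
               dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  diag(bc) <- 0
  env <- setNames(c("ENV_A", "ENV_A", "ENV_B", "ENV_B"), paste0("s", 1:4))
  gr <- beta_diversity_groups(bc, env)
  expect_equal(length(gr$within_ENV_A), 1L)
  expect_equal(length(gr$within_ENV_B), 1L)
  expect_equal(length(gr$between), 4L)

  # planted structure: between strictly above within gives a small p
  set.seed(45)
  n <- 6
  ab <- cbind(matrix(rexp(4 * n, 1 / 10), 4, n), matrix(0, 4, n))
  ab <- rbind(ab, cbind(matrix(0, 4, n), matrix(rexp(4 * n, 1 / 10), 4, n)))
  colnames(ab) <- sprintf("s%02d", 1:(2 * n))
  rownames(ab) <- sprintf("F%02d", 1:8)
  env2 <- setNames(rep(c("ENV_A", "ENV_B"), each = n), colnames(ab))
  gr2 <- beta_diversity_groups(bc_matrix(ab), env2)
  expect_true(all(gr2$between > max(gr2$within_ENV_A, gr2$within_ENV_B)))
  expect_lt(gr2$p_value, 0.05)

  expect_error(beta_diversity_groups(bc, setNames(rep("ENV_A", 4),
                                                  paste0("s", 1:4))),
               "two environment")
})
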
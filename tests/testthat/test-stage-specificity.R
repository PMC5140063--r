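test_that("entropy score matches the formula on worked examples", {
  expect_equal(entropy_score(c(10, 0, 0, 0, 0))$H, 0)
  expect_equal(entropy_score(c(5, 5, 5, 5, 5))$H, log2(5))
  expect_equal(entropy_score(c(8, 2, 0, 0, 0))$H, 0.721928,
               tolerance = 1e-6)
  expect_error(entropy_score(c(1, -1)), ">= 0")
  # silent features carry an undefined score
  expect_true(is.na(entropy_score(c(0, 0, 0))$H))
  # relative expression sums to one
  expect_equal(sum(entropy_score(c(3, 1, 7, 2, 9))$R), 1)
})

test_that("entropy is scale invariant and permutation invariant", {
  set.seed(51)
  for (k in 1:50) {
    e <- runif(5, 0, 100)
    h <- entropy_score(e)$H
    expect_equal(entropy_score(e * runif(1, 0.01, 50))$H, h)
    perm <- sample(5)
    ep <- entropy_score(e[perm])
    expect_equal(ep$H, h)
    expect_equal(ep$R, (e / sum(e))[perm])
  }
})

test_that("matrix entropy agrees with the vector form", {
  set.seed(52)
  m <- matrix(runif(40, 0, 50), 8, 5)
  m[3, ] <- 0
  h <- entropy_score(m)
  for (i in seq_len(8)) {
    expect_equal(h[i], entropy_score(m[i, ])$H)
  }
})

test_that("stage-specific gene selection applies all three predicates", {
  stages <- c("d-3", "d0", "6h", "d2", "d7")
  m <- rbind(
    one_stage = c(50, 0.1, 0.1, 0.1, 0.1),  # assigned to d-3 only
    uniform = c(6, 6, 6, 6, 6),              # entropy and breadth fail
    two_stage = c(50, 8, 0.1, 0.1, 0.1)      # assigned to d-3 and d0
  )
  colnames(m) <- stages
  got <- select_stage_specific(m, "coding")
  expect_setequal(paste(got$feature_id, got$stage),
                  c("one_stage d-3", "two_stage d-3", "two_stage d0"))
  expect_true(all(got$H < 2))

  # lncRNA threshold is 0.5
  lm <- rbind(lnc1 = c(2, 0.1, 0.1, 0.1, 0.1))
  colnames(lm) <- stages
  got <- select_stage_specific(lm, "lncRNA")
  expect_equal(got$stage, "d-3")

  expect_error(select_stage_specific(m, "protein"), "unknown feature class")
  expect_error(select_stage_specific(m, "miRNA"), "expr_min")
})

test_that("selection equals a brute-force per-feature predicate", {
  set.seed(53)
  n <- 400
  m <- matrix(rexp(n * 5, 1 / 8), n, 5,
              dimnames = list(sprintf("f%03d", 1:n), paste0("s", 1:5)))
  m[sample(length(m), 300)] <- 0
  got <- select_stage_specific(m, "coding")
  got_keys <- sort(paste(got$feature_id, got$stage))
  exp_keys <- character()
  for (i in seq_len(n)) {
    e <- m[i, ]
    if (sum(e) == 0) next
    h <- bf_entropy(e)
    for (j in 1:5) {
      if (h < 2 && e[j] > 5 && sum(e[-j] > 5) <= 3) {
        exp_keys <- c(exp_keys, paste(rownames(m)[i], colnames(m)[j]))
      }
    }
  }
  expect_equal(got_keys, sort(exp_keys))
})

test_that("quantile normalization equalizes column distributions", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))

  # identical columns are a fixed point
  m2 <- cbind(a = c(9, 1, 5), b = c(9, 1, 5))
  expect_equal(quantile_normalize(m2), m2)

  set.seed(54)
  m3 <- matrix(rlnorm(60, 5, 1), 12, 5)
  qn3 <- quantile_normalize(m3)
  expect_equal(diff(range(colMeans(qn3))), 0, tolerance = 1e-12)
})

test_that("miRNA selection uses strict fold and argmax stage", {
  stages <- paste0("s", 1:5)
  m <- rbind(flat = c(10, 10, 10, 10, 10),
             up3 = c(30, 10, 10, 10, 10),
             up2 = c(20, 10, 10, 10, 10))
  colnames(m) <- stages
  got <- select_stage_specific_mirna(m)
  expect_equal(got$feature_id, "up3")
  expect_equal(got$stage, "s1")
  expect_false(got$tie)

  # detection floor bounds the denominator
  m2 <- rbind(lowfloor = c(1.5, 0.01, 0.01, 0.01, 0.01))
  colnames(m2) <- stages
  expect_equal(nrow(select_stage_specific_mirna(m2, floor = 1)), 0)
  expect_equal(nrow(select_stage_specific_mirna(m2, floor = 0.5)), 1)

  # argmax ties are flagged and resolved to the earliest stage
  m3 <- rbind(tie = c(30, 30, 10, 10, 10))
  colnames(m3) <- stages
  got <- select_stage_specific_mirna(m3)
  expect_equal(got$stage, "s1")
  expect_true(got$tie)
})

test_that("transient-induction selection requires rise, fall and expression", {
  stages <- c("d-3", "d0", "6h", "d2", "d7")
  m <- rbind(transient = c(1, 10, 1, 1, 1),
             monotone = c(1, 2, 4, 8, 16),
             flat = c(5, 5, 5, 5, 5),
             weak = c(1, 4, 1, 1, 1))   # induced but below expr_min
  colnames(m) <- stages
  expect_equal(select_bmp7_transient(m), "transient")
  expect_error(select_bmp7_transient(m[, 1:2, drop = FALSE]),
               "required stages absent")
})
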
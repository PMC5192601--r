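# exact rational kernel

test_that("rational parse/format round trip is the identity", {
  cases <- c("0", "1", "-3", "1/3", "-7/12", "0.25", "1.592", "5e-2",
             "3.26e7")
  for (tx in cases) {
    q <- plantflux:::rq_parse(tx)
    q2 <- plantflux:::rq_parse(plantflux:::rq_format(q))
    expect_identical(q, q2, label = tx)
  }
  expect_error(plantflux:::rq_parse("abc"), "cannot parse")
})

test_that("arithmetic stays exact on adversarial decimals", {
  a <- plantflux:::rq_parse("0.1")
  acc <- plantflux:::rq_scalar(0)
  for (i in 1:10) acc <- plantflux:::rq_add(acc, a)
  expect_identical(plantflux:::rq_format(acc), "1")   # 10 * 0.1 == 1 exactly
  b <- plantflux:::rq_mul(plantflux:::rq_parse("1/3"),
                          plantflux:::rq_parse("3/7"))
  expect_identical(plantflux:::rq_format(b), "1/7")
})

test_that("rref rank and nullspace are exact on random rational matrices", {
  set.seed(42)
  for (rep in 1:25) {
    nr <- sample(2:5, 1); nc <- sample(2:6, 1)
    N <- matrix(sample(-6:6, nr * nc, TRUE), nr, nc)
    D <- matrix(sample(c(1, 1, 2, 3, 4), nr * nc, TRUE), nr, nc)
    M <- plantflux:::rq_mat(N, D)
    B <- plantflux:::rq_nullspace(plantflux:::rq_mat_integerise(M, 1L))
    rk <- plantflux:::rq_rref(M)$rank
    expect_equal(ncol(B) + rk, nc)
    if (ncol(B)) {
      for (j in seq_len(ncol(B))) {
        resid <- plantflux:::rq_matvec_int(M, B[, j])
        expect_true(all(resid$n == 0))   # exact, not approximate
      }
    }
  }
})

test_that("overflow is detected, never silently lost", {
  expect_error(plantflux:::rq(2^53, 1), "overflow")
})
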
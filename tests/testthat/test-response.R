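test_that("expression floor acts on the posterior median, not per draw", {
  expect_equal(floor_expression(c(0.001, 0.002), 0.01), c(0.01, 0.01))
  expect_equal(floor_expression(c(5, 6), 0.01), c(5, 6))
  # median 50.0025 >= c, so the low draw survives untouched
  expect_equal(floor_expression(c(0.005, 100), 0.01), c(0.005, 100))
  # idempotence
  for (draws in list(c(0.001, 0.002), c(5, 6), runif(10, 0, 0.02))) {
    once <- floor_expression(draws, 0.01)
    expect_identical(floor_expression(once, 0.01), once)
  }
})

test_that("response and error variance reproduce hand-computed values", {
  # log(2.70828 + 0.01) = 1, log(0.99 + 0.01) = 0 exactly
  r <- build_response(pat = matrix(exp(1) - 0.01, 2, 1),
                      mat = matrix(0.99, 2, 1), mode = "diff", floor_c = 0.01)
  expect_equal(r$y_hat, 1, tolerance = 1e-12)
  expect_equal(r$err_var, 0, tolerance = 1e-12)

  # per-draw log differences {1, 3}: mean 2, variance (1 + 1)/(2 - 1) = 2
  pat <- matrix(exp(c(1, 3)) - 0.01, 2, 1)
  mat <- matrix(1 - 0.01, 2, 1)
  r <- build_response(pat, mat, "diff", 0.01)
  expect_equal(r$y_hat, 2, tolerance = 1e-12)
  expect_equal(r$err_var, 2, tolerance = 1e-12)

  # symmetric input
  m <- matrix(runif(20, 1, 5), 4, 5)
  r <- build_response(m, m, "diff")
  expect_equal(r$y_hat, rep(0, 5))
  expect_equal(r$err_var, rep(0, 5))

  expect_error(build_response(m[1, , drop = FALSE], m[1, , drop = FALSE]),
               "S = 2")
})

test_that("allele swap negates the difference response and fixes the overall one", {
  set.seed(31)
  pat <- matrix(rexp(60, 0.5), 6, 10)
  mat <- matrix(rexp(60, 0.5), 6, 10)
  fwd <- build_response(pat, mat, "diff")
  rev <- build_response(mat, pat, "diff")
  expect_equal(rev$y_hat, -fwd$y_hat)
  expect_equal(rev$err_var, fwd$err_var)
  tot_f <- build_response(pat, mat, "overall")
  tot_r <- build_response(mat, pat, "overall")
  expect_equal(tot_f$y_hat, tot_r$y_hat)
})

test_that("response scaling gives unit standard deviation and transforms variances", {
  s <- scale_response(c(1, -1), c(4, 4))
  expect_equal(s$scale_sd, sqrt(2))
  expect_equal(s$y_scaled, c(1, -1) / sqrt(2), tolerance = 1e-9)
  expect_equal(s$err_var_scaled, c(2, 2))
  expect_warning(out <- scale_response(c(2, 2, 2), c(1, 1, 1)), "zero standard deviation")
  expect_null(out)
  set.seed(5)
  for (k in 1:5) {
    y <- rnorm(12); e <- runif(12)
    sc <- scale_response(y, e)
    expect_equal(sd(sc$y_scaled), 1, tolerance = 1e-12)
    expect_true(all(sc$err_var_scaled >= 1e-8))
  }
})

test_that("design matrix follows the +1 F1i/male/P8 coding and is orthogonal when balanced", {
  one <- tibble::tibble(sample_id = "a", cross = "F1i", sex = "male", age = "P8")
  two <- tibble::tibble(sample_id = "b", cross = "F1r", sex = "female", age = "P60")
  X <- build_design_matrix(dplyr::bind_rows(one, two))
  expect_equal(unname(X[1, ]), c(1, 1, 1, 1))
  expect_equal(unname(X[2, ]), c(1, -1, -1, -1))
  expect_equal(colnames(X), c("parental", "cross", "sex", "age"))

  Xb <- build_design_matrix(sim_design(6))
  expect_equal(unname(crossprod(Xb)), diag(48, 4))

  # single-age subsets must drop the age column explicitly
  p8 <- dplyr::filter(sim_design(6), age == "P8")
  expect_error(build_design_matrix(p8), "single observed level")
  expect_equal(colnames(build_design_matrix(p8, c("cross", "sex"))),
               c("parental", "cross", "sex"))
})

test_that("cohort-level response sets skip constant transcripts and honour the stringent filter", {
  design <- sim_design(2)
  # one expressed transcript, one fully floored (constant response)
  entries <- purrr::map(design$sample_id, \(s) list(
    list("expr", "g1", s, "paternal", c(2, 2.2)),
    list("expr", "g1", s, "maternal", c(1, 1.1)),
    list("dead", "g2", s, "paternal", c(0.001, 0.001)),
    list("dead", "g2", s, "maternal", c(0.001, 0.002))
  )) |> purrr::flatten()
  tab <- make_posterior_tbl(entries)
  # perturb one expressed sample so its response is not constant
  tab$tpm[tab$transcript_id == "expr" & tab$sample_id == "s01" &
            tab$allele == "paternal"] <- c(3, 3.3)
  suppressMessages(rs <- build_response_set(tab, design))
  expect_equal(rs$skipped[rs$transcript_id == "dead"], TRUE)
  expect_equal(rs$skipped[rs$transcript_id == "expr"], FALSE)
  expect_equal(sd(rs$y_scaled[[which(rs$transcript_id == "expr")]]), 1,
               tolerance = 1e-12)

  # stringent filter removes the floored transcript entirely
  suppressMessages(
    rs2 <- build_response_set(tab, design, stringent_cutoff = -1.6)
  )
  expect_false("dead" %in% rs2$transcript_id)
  expect_true("expr" %in% rs2$transcript_id)
})

test_that("age-expression flags mark exclusively expressed transcripts", {
  design <- sim_design(1)
  entries <- purrr::map(design$sample_id, \(s) {
    is_p8 <- design$age[design$sample_id == s] == "P8"
    lvl <- if (is_p8) c(2, 2.2) else c(0.001, 0.002)
    list(
      list("p8only", "g", s, "paternal", lvl),
      list("p8only", "g", s, "maternal", lvl)
    )
  }) |> purrr::flatten()
  flags <- expressed_by_age(make_posterior_tbl(entries), design)
  expect_true(flags$expressed_P8)
  expect_false(flags$expressed_P60)
})
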
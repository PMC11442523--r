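test_that("discretization recovers uniform masses and handles tails", {
  set.seed(21)
  n <- 4e4
  g <- rb_grid(0, 1, 0.25, align = FALSE)
  prof <- discretize(runif(n), runif(n), g)
  tol <- 3 * sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(prof$prior_mass - 0.25) < tol))
  expect_true(all(abs(prof$posterior_mass - 0.25) < tol))

  # draws outside the grid are tallied as tail mass, not dropped silently
  prof2 <- discretize(c(runif(n), rep(5, n)), runif(n), g)
  expect_equal(attr(prof2, "prior_tail"), 0.5, tolerance = 1e-9)
  expect_equal(sum(prof2$prior_mass), 0.5, tolerance = 1e-9)
})

test_that("identical prior and posterior draws yield the no-evidence event", {
  set.seed(22)
  x <- rnorm(5000)
  prof <- relative_belief(discretize(x, x, rb_grid(-3, 3, 0.5)))
  expect_true(all(prof$rb[prof$included] == 1))
  expect_true(attr(prof, "no_evidence"))
  expect_message(pl <- plausible_region(prof), "no evidence")
  expect_length(pl$bins, 0)
  expect_true(pl$no_evidence)
  expect_true(is.na(pl$estimate))
})

test_that("relative belief ratios are the mass ratios and normalize", {
  p <- mass_profile(c(0.5, 1.5), c(0.5, 0.5), c(0.25, 0.75))
  expect_equal(relative_belief(p)$rb, c(0.5, 1.5))

  p3 <- relative_belief(mass_profile(1:3, c(0.2, 0.3, 0.5), c(0.1, 0.3, 0.6)))
  expect_equal(p3$rb, c(0.5, 1.0, 1.2))
  expect_equal(sum(p3$rb * p3$prior_mass), 1, tolerance = 1e-12)

  expect_error(relative_belief(mass_profile(1:2, c(0, 0), c(0.5, 0.5))),
               "zero prior mass")
})

test_that("normalization identity and never-improper properties hold on random profiles", {
  set.seed(23)
  for (i in 1:200) {
    prof <- relative_belief(random_profile(sample(2:30, 1)))
    inc <- prof$included
    expect_equal(sum(prof$rb[inc] * prof$prior_mass[inc]),
                 sum(prof$posterior_mass), tolerance = 1e-9)
    # evidence in favor of every value at once is impossible
    expect_false(all(prof$rb[inc] > 1))
    # and unless there is no evidence at all, some value has evidence in favor
    if (!all(prof$rb[inc] == 1)) {
      expect_gt(length(plausible_region(prof)$bins), 0)
    }
  }
  # high-volume check of the impossibility, vectorized
  k <- 20
  w1 <- matrix(rgamma(1e4 * k, 1), ncol = k)
  w2 <- matrix(rgamma(1e4 * k, 1), ncol = k)
  rb <- (w2 / rowSums(w2)) / (w1 / rowSums(w1))
  expect_equal(sum(apply(rb > 1, 1, all)), 0)
})

test_that("zero-prior bins are excluded from every region", {
  prof <- relative_belief(
    mass_profile(1:4, c(0.5, 0, 0.3, 0.2), c(0.2, 0.3, 0.1, 0.4))
  )
  expect_true(is.na(prof$rb[2]))
  expect_false(2L %in% plausible_region(prof)$bins)
  expect_false(2L %in% implausible_region(prof)$bins)
  expect_false(2L %in% credible_region(prof, 0.9)$bins)
})

test_that("plausible and implausible regions split by the evidence cut-off", {
  prof <- relative_belief(mass_profile(1:3, c(0.2, 0.3, 0.5), c(0.1, 0.3, 0.6)))
  pl <- plausible_region(prof)
  im <- implausible_region(prof)
  expect_equal(pl$bins, 3L)
  expect_equal(im$bins, 1L)           # rb exactly 1 is in neither region
  expect_equal(pl$estimate, 3)
  expect_equal(pl$posterior_content, 0.6)
  expect_equal(pl$prior_content, 0.5)
  # non-adjacent plausible bins are reported as separate intervals
  prof2 <- relative_belief(
    mass_profile(1:5, rep(0.2, 5), c(0.4, 0.05, 0.05, 0.3, 0.2))
  )
  expect_equal(nrow(plausible_region(prof2)$intervals), 2)
})

test_that("argmax ties break to the lowest bin with a message", {
  prof <- relative_belief(mass_profile(1:3, c(0.4, 0.4, 0.2), c(0.5, 0.5, 0)))
  expect_message(pl <- plausible_region(prof), "tie")
  expect_equal(pl$estimate, 1)
})

test_that("credible regions match a brute-force threshold search", {
  prof <- relative_belief(mass_profile(1:3, c(0.2, 0.3, 0.5), c(0.1, 0.3, 0.6)))
  cr <- credible_region(prof, 0.55)
  expect_equal(cr$bins, 3L)            # posterior mass 0.6 >= 0.55
  expect_gte(cr$posterior_content, 0.55)

  brute_force <- function(prof, gamma) {
    # largest r with rejected posterior mass <= 1 - gamma, by enumeration
    cand <- sort(unique(prof$rb))
    keep <- cand[vapply(cand, function(r) {
      sum(prof$posterior_mass[prof$rb < r]) <= 1 - gamma
    }, logical(1))]
    r <- max(keep)
    which(prof$rb >= r)
  }
  set.seed(24)
  for (i in 1:50) {
    prof <- relative_belief(random_profile(sample(3:15, 1)))
    gamma <- runif(1, 0.2, 0.95)
    cr <- credible_region(prof, gamma)
    expect_equal(cr$bins, brute_force(prof, gamma))
    expect_gte(cr$posterior_content, gamma)
    # containment in the plausible region whenever gamma allows it
    pl <- plausible_region(prof)
    if (gamma <= pl$posterior_content && length(pl$bins) > 0) {
      expect_true(all(cr$bins %in% pl$bins))
    }
  }
})

test_that("gamma near 1 returns every bin with posterior mass", {
  prof <- relative_belief(mass_profile(1:4, rep(0.25, 4), c(0.4, 0.3, 0.3, 0)))
  cr <- credible_region(prof, 0.9999)
  expect_true(all(which(prof$posterior_mass > 0) %in% cr$bins))
})

test_that("affine reparameterization leaves bin membership invariant", {
  set.seed(25)
  x_prior <- rnorm(2e4)
  x_post <- rnorm(2e4, 0.4, 0.8)
  g <- rb_grid(-3, 3, 0.5, align = FALSE)
  prof <- relative_belief(discretize(x_prior, x_post, g))

  a <- 2.5; b <- -1
  g2 <- rb_grid(a * -3 + b, a * 3 + b, a * 0.5, align = FALSE)
  prof2 <- relative_belief(discretize(a * x_prior + b, a * x_post + b, g2))

  expect_equal(prof2$prior_mass, prof$prior_mass)
  expect_equal(prof2$posterior_mass, prof$posterior_mass)
  pl1 <- plausible_region(prof)
  pl2 <- plausible_region(prof2)
  expect_equal(pl1$bins, pl2$bins)
  expect_equal(pl2$intervals$lower, a * pl1$intervals$lower + b)
  expect_equal(pl2$estimate, a * pl1$estimate + b)
})

test_that("profile accessors and plots work", {
  set.seed(26)
  prof <- relative_belief(discretize(rnorm(5000), rnorm(5000, 0.5),
                                     rb_grid(-3, 3, 0.5)))
  expect_s3_class(glance(prof), "tbl_df")
  expect_s3_class(autoplot(prof), "ggplot")
  pl <- plausible_region(prof)
  expect_s3_class(tidy(pl), "tbl_df")
  expect_equal(glance(pl)$posterior_content, pl$posterior_content)
})
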
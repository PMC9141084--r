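test_that("marginal stability derivatives match corner eigenvalues", {
  expect_equal(stability_derivative(baseline, c(0, 0, 0), "government"),
               1.85)
  expect_equal(stability_derivative(baseline, c(1, 1, 1), "institution"),
               -0.75)
  # the (1 - 2s) factor kills the derivative at a half-mixed population
  for (pl in c("government", "enterprise", "institution"))
    expect_equal(stability_derivative(baseline, c(0.5, 0.5, 0.5), pl), 0)
})

test_that("analytic Jacobian is diagonal at corners, matches FD inside", {
  J <- game_jacobian(baseline, c(0, 1, 1))
  expect_equal(unname(diag(J)), c(-0.45, -1.25, -0.45))
  expect_equal(unname(J[row(J) != col(J)]), rep(0, 6))
  for (i in 1:100) {
    p <- random_parameters(seed = 400 + i)
    for (s in corner_states) {
      J <- game_jacobian(p, s)
      expect_identical(unname(J[row(J) != col(J)]), rep(0, 6))
    }
  }
  # oracle equivalence at random interior points, both variants
  set.seed(5)
  for (i in 1:20) {
    p <- random_parameters(seed = 500 + i)
    s <- random_interior_state()
    for (v in c("as_printed", "table2_consistent"))
      expect_equal(game_jacobian(p, s, v), fd_jacobian(p, s, v),
                   tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("equilibrium classification reproduces the published table", {
  rep <- classify_equilibria(baseline)
  expect_equal(rep$point, published_table4$point)
  expect_equal(rep$eigen_gov, published_table4$e1, tolerance = 1e-12)
  expect_equal(rep$eigen_ent, published_table4$e2, tolerance = 1e-12)
  expect_equal(rep$eigen_inst, published_table4$e3, tolerance = 1e-12)
  expect_equal(rep$attribute, published_table4$attribute)
  expect_equal(which(rep$attribute == "stable"), 7L)  # only O7 is an ESS
})

test_that("constructed zero eigenvalue is labelled non-hyperbolic", {
  # choose H so the government factor vanishes at (1, 1, 1):
  # H + f1 - CG - GH - f1 - GC = 0  =>  H = CG + GH + GC
  p <- game_parameters(H = 0.05 + 0.2 + 2)
  rep <- classify_equilibria(p)
  expect_equal(rep$attribute[rep$point == "O8"], "non_hyperbolic")
})

test_that("equilibrium report serializes to JSON and text", {
  dir <- withr::local_tempdir()
  rep <- classify_equilibria(baseline)
  jpath <- file.path(dir, "eq.json")
  write_equilibrium_report(rep, jpath)
  back <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(nrow(back), 8L)
  expect_equal(back$eigenvalues[[7]], c(-0.45, -1.25, -0.45))
  expect_equal(back$attribute[7], "stable")
  txt <- format(rep)
  expect_length(txt, 9L)  # header + 8 corners
  expect_match(txt[8], "O7.*stable")
})

test_that("regulation thresholds follow the indifference formulas", {
  thr <- regulation_thresholds(baseline, y = 0, z = 0)
  expect_equal(thr$lambda_y, 1.85 / 2)
  expect_equal(thr$lambda_z, 1.85 / 0.3)   # > 1: regulate for every z
  expect_error(regulation_thresholds(game_parameters(GC = 0), 0, 0),
               "degenerate")
  # monotone: thresholds non-increasing in the opponent proportion
  set.seed(3)
  for (i in 1:20) {
    p <- random_parameters(seed = 600 + i)
    a <- regulation_thresholds(p, y = 0.2, z = 0.2)
    b <- regulation_thresholds(p, y = 0.8, z = 0.8)
    expect_lte(b$lambda_y, a$lambda_y + 1e-12)
    expect_lte(b$lambda_z, a$lambda_z + 1e-12)
  }
})

test_that("enterprise and institution rate factors are monotone in allies", {
  # enterprise factor non-decreasing in x and z; institution in x and y
  set.seed(4)
  for (i in 1:20) {
    p <- unclass(random_parameters(seed = 700 + i))
    expect_gte(p[["GC"]] * p[["q"]], 0)                      # d(ent)/dx
    expect_gte((p[["alpha"]] * p[["P"]] - p[["f2"]] + p[["P"]]) *
                 p[["q"]], -1e-12)                           # d(ent)/dz *
    expect_gte((p[["GH"]] + p[["f1"]]) * p[["q"]], 0)        # d(inst)/dx
    expect_gte(p[["f2"]] * p[["q"]], 0)                      # d(inst)/dy
  }
  # (*) table2_consistent coefficient alpha P - f2 + P; as_printed drops P
  # but sampling keeps alpha P >= f2 here, so both are non-negative.
})

test_that("critical reputation loss and the dominance predicate agree", {
  expect_equal(critical_reputation_loss(baseline, "given_y", 0), 0.25)
  expect_equal(critical_reputation_loss(baseline, "given_y", 1), 2.25)
  expect_equal(critical_reputation_loss(baseline, "given_z", 1),
               0.05 + 2 + 0.2)
  set.seed(9)
  for (i in 1:40) {
    p <- random_parameters(seed = 800 + i)
    prop <- runif(1)
    if (regulation_dominant(p, "given_y", prop))
      expect_gt(regulation_thresholds(p, y = prop)$lambda_z, 1)
    if (regulation_dominant(p, "given_z", prop))
      expect_gt(regulation_thresholds(p, z = prop)$lambda_y, 1)
  }
})

test_that("midpoint region proportions match hand evaluation", {
  rp <- region_proportions(baseline)
  expect_equal(rp$v11, 1.7 / 0.6)
  expect_equal(rp$v12, (1.85 - 0.15) / 2)
  expect_equal(rp$w21, 1 - (0.2 + 1.5 + 0.6 - 2 - 1.5) / 4)
  expect_equal(rp$w22, 1 - (1.5 + 0.6 - 2 - 2) / 2.6)
  expect_equal(rp$w31, 1 - (3 + 0.1 - 4 + 0.2) / 0.6)
  expect_equal(rp$w32, 1 - (3 + 0.1 - 4 + 0.4 - 0.2 - 0.1) / 0.4)
  clipped <- region_proportions(baseline, clip = TRUE)$clipped
  expect_true(all(unlist(clipped) >= 0 & unlist(clipped) <= 1))
  expect_error(region_proportions(game_parameters(f2 = 0)), "degenerate")
})

test_that("strict-print forms differ only where the print is inconsistent", {
  rp <- region_proportions(baseline)
  sp <- region_proportions(baseline, strict_print = TRUE)
  expect_equal(sp$v11, rp$v11)
  expect_equal(sp$w21, rp$w21)
  expect_equal(sp$w22, rp$w22)
  expect_equal(sp$v12, 3.45 / 4)              # printed literal
  expect_equal(sp$w31, 1 - (3 + 0.1 + 4 + 0.2) / 0.6)  # rc sign flipped
  expect_false(isTRUE(all.equal(sp$w32, rp$w32)))
})

test_that("threshold identities hold for random parameter sets", {
  for (i in 1:50) {
    p <- random_parameters(seed = 900 + i)
    rp <- region_proportions(p)
    thr <- regulation_thresholds(p, y = 0.5, z = 0.5)
    expect_equal(rp$v11, thr$lambda_z, tolerance = 1e-12)
    expect_equal(rp$v12, thr$lambda_y, tolerance = 1e-12)
    # w's are one minus the indifference root at opponent proportion 1/2
    pr <- unclass(p)
    root <- function(player, fixed, value) {
      # solve rate_factor == 0 for the free proportion
      f0 <- function(free) {
        s <- switch(paste(player, fixed),
          "enterprise z" = c(free, 0.5, value),
          "enterprise x" = c(value, 0.5, free),
          "institution y" = c(free, value, 0.5),
          "institution x" = c(value, free, 0.5))
        # bypass strategy_state(): roots may fall outside [0, 1]
        rate_factor(pr, c(x = s[1], y = s[2], z = s[3]), player,
                    "as_printed") / pr[["q"]]
      }
      stats::uniroot(f0, c(-50, 50), extendInt = "yes",
                     tol = 1e-12)$root
    }
    expect_equal(rp$w21, 1 - root("enterprise", "z", 0.5), tolerance = 1e-8)
    expect_equal(rp$w22, 1 - root("enterprise", "x", 0.5), tolerance = 1e-8)
    expect_equal(rp$w31, 1 - root("institution", "y", 0.5), tolerance = 1e-8)
    expect_equal(rp$w32, 1 - root("institution", "x", 0.5), tolerance = 1e-8)
  }
})

test_that("sensitivity signs reproduce the published correlation column", {
  signs <- sensitivity_signs(baseline)
  expect_equal(nrow(signs), 17L)
  expect_equal(signs$sign, signs$expected_sign)
  rc_row <- signs[signs$quantity == "w31" & signs$parameter == "rc", ]
  expect_equal(rc_row$sign, "+")
  # a parameter absent from a quantity has derivative zero
  extra <- sensitivity_signs(baseline,
                             pairs = data.frame(quantity = "v11",
                                                parameter = "P"))
  expect_equal(extra$sign, "0")
})
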
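#' Marginal stability derivative of one player
#'
#' The derivative of a player's replicator rate with respect to its own
#' proportion, `(1 - 2s) * (U1 - U2)`, evaluated at `state`.  At a
#' pure-strategy corner this is that player's Jacobian eigenvalue.
#'
#' @inheritParams replicator_rate
#' @return A single value (per unit time).
#' @export
stability_derivative <- function(params, state, player,
                                 variant = c("as_printed",
                                             "table2_consistent")) {
  player <- match.arg(player, PLAYERS)
  variant <- match.arg(variant)
  p <- unclass(validate_parameters(params))
  s <- as_strategy_state(state)
  share <- switch(player, government = s[["x"]], enterprise = s[["y"]],
                  institution = s[["z"]])
  (1 - 2 * share) * rate_factor(p, s, player, variant)
}

#' Analytic Jacobian of the replicator field
#'
#' Partial derivatives of the three replicator rates with respect to
#' (x, y, z).  At any pure-strategy corner the factors `s(1-s)` kill every
#' off-diagonal entry, so the diagonal holds the three eigenvalues used to
#' classify the corner.
#'
#' @inheritParams replicator_rate
#' @return A 3x3 numeric matrix with dimnames `x`, `y`, `z` (rows: rates,
#'   columns: differentiation variable).
#' @export
game_jacobian <- function(params, state,
                          variant = c("as_printed", "table2_consistent")) {
  variant <- match.arg(variant)
  p <- unclass(validate_parameters(params))
  s <- as_strategy_state(state)
  x <- s[["x"]]; y <- s[["y"]]; z <- s[["z"]]
  q <- p[["q"]]
  gx <- rate_factor(p, s, "government", variant)
  gy <- rate_factor(p, s, "enterprise", variant)
  gz <- rate_factor(p, s, "institution", variant)
  dgy_dz <- if (variant == "as_printed") {
    (p[["alpha"]] * p[["P"]] - p[["f2"]]) * q
  } else {
    (p[["alpha"]] * p[["P"]] - p[["f2"]] + p[["P"]]) * q
  }
  J <- matrix(c(
    (1 - 2 * x) * gx, -x * (1 - x) * p[["GC"]] * q,
    -x * (1 - x) * (p[["GH"]] + p[["f1"]]) * q,
    y * (1 - y) * p[["GC"]] * q, (1 - 2 * y) * gy, y * (1 - y) * dgy_dz,
    z * (1 - z) * (p[["GH"]] + p[["f1"]]) * q, z * (1 - z) * p[["f2"]] * q,
    (1 - 2 * z) * gz
  ), nrow = 3, byrow = TRUE, dimnames = list(c("x", "y", "z"),
                                             c("x", "y", "z")))
  J
}

# The eight pure-strategy corners in the conventional O1..O8 order.
PURE_CORNERS <- matrix(c(0, 0, 0,  1, 0, 0,  0, 1, 0,  0, 0, 1,
                         1, 1, 0,  1, 0, 1,  0, 1, 1,  1, 1, 1),
                       ncol = 3, byrow = TRUE,
                       dimnames = list(paste0("O", 1:8), c("x", "y", "z")))

#' Classify the eight pure-strategy equilibria
#'
#' Every corner of the unit cube is a fixed point of the replicator field.
#' Each is classified by the sign pattern of its three Jacobian
#' eigenvalues (all off-diagonal Jacobian entries vanish at corners):
#' `stable` (an ESS) iff all three are negative, `non_hyperbolic` if any is
#' zero within `zero_tol`, and `saddle` otherwise (mirroring the field's
#' convention of labelling every non-stable corner a saddle, sources
#' included).
#'
#' @inheritParams replicator_rate
#' @param zero_tol absolute tolerance below which an eigenvalue is treated
#'   as zero (default 1e-9).
#' @return A data frame of class `equilibrium_report` with one row per
#'   corner (order O1..O8): columns `point`, `x`, `y`, `z`, `eigen_gov`,
#'   `eigen_ent`, `eigen_inst`, `attribute`.
#' @examples
#' classify_equilibria(game_parameters())
#' @export
classify_equilibria <- function(params,
                                variant = c("as_printed",
                                            "table2_consistent"),
                                zero_tol = 1e-9) {
  variant <- match.arg(variant)
  params <- validate_parameters(params)
  rows <- lapply(seq_len(nrow(PURE_CORNERS)), function(i) {
    corner <- strategy_state(PURE_CORNERS[i, 1], PURE_CORNERS[i, 2],
                             PURE_CORNERS[i, 3])
    ev <- diag(game_jacobian(params, corner, variant))
    attribute <- if (any(abs(ev) < zero_tol)) "non_hyperbolic"
                 else if (all(ev < 0)) "stable" else "saddle"
    data.frame(point = rownames(PURE_CORNERS)[i],
               x = corner[["x"]], y = corner[["y"]], z = corner[["z"]],
               eigen_gov = ev[["x"]], eigen_ent = ev[["y"]],
               eigen_inst = ev[["z"]], attribute = attribute)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("equilibrium_report", "data.frame")
  out
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.equilibrium_report <- function(x, ...) {
  hdr <- sprintf("%-12s %9s %9s %9s  %s", "Equilibrium", "e1", "e2", "e3",
                 "Attribute")
  body <- sprintf("%-12s %9.4g %9.4g %9.4g  %s",
                  sprintf("%s(%d, %d, %d)", x$point, x$x, x$y, x$z),
                  x$eigen_gov, x$eigen_ent, x$eigen_inst, x$attribute)
  c(hdr, body)
}

#' Serialize an equilibrium report to JSON
#'
#' Writes a list of `{corner, eigenvalues, attribute}` records.
#'
#' @param report an `equilibrium_report` from [classify_equilibria()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_equilibrium_report <- function(report, path) {
  recs <- lapply(seq_len(nrow(report)), function(i) {
    list(point = report$point[i],
         corner = c(report$x[i], report$y[i], report$z[i]),
         eigenvalues = c(report$eigen_gov[i], report$eigen_ent[i],
                         report$eigen_inst[i]),
         attribute = report$attribute[i])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Government regulation-indifference thresholds
#'
#' The government is indifferent between regulating and not when its
#' payoff-advantage factor vanishes.  Solving for each opponent proportion
#' gives \deqn{\lambda_y = (H + f_1 - C_G - z(G_H + f_1)) / G_C}
#' (regulation favored for `y` below this, given `z`) and
#' \deqn{\lambda_z = (H + f_1 - C_G - y G_C) / (f_1 + G_H)}
#' (regulation favored for `z` below this, given `y`).  Values outside
#' \[0, 1\] mean one regime holds for every proportion.
#'
#' @param params a [game_parameters()] object.
#' @param y,z opponent proportions in \[0, 1\].
#' @return List with `lambda_y` (uses `z`) and `lambda_z` (uses `y`),
#'   dimensionless and unclipped.
#' @export
regulation_thresholds <- function(params, y = 0, z = 0) {
  p <- unclass(validate_parameters(params))
  stopifnot(y >= 0, y <= 1, z >= 0, z <= 1)
  if (p[["GC"]] == 0 || p[["f1"]] + p[["GH"]] == 0)
    stop("degenerate thresholds: need GC > 0 and f1 + GH > 0",
         call. = FALSE)
  list(
    lambda_y = (p[["H"]] + p[["f1"]] - p[["CG"]] -
                  z * (p[["GH"]] + p[["f1"]])) / p[["GC"]],
    lambda_z = (p[["H"]] + p[["f1"]] - p[["CG"]] - y * p[["GC"]]) /
      (p[["f1"]] + p[["GH"]])
  )
}

#' Critical reputation loss
#'
#' The reputation-damage level above which regulating dominates for the
#' government regardless of the remaining player's mixing:
#' `CG + GC + GH - GC (1 - y)` (mode `given_y`; dominance over
#' institutions' choice) or `CG + GC + GH - (GH + f1)(1 - z)` (mode
#' `given_z`; dominance over enterprises' choice).
#'
#' @param params a [game_parameters()] object.
#' @param mode `"given_y"` or `"given_z"`.
#' @param proportion the known opponent proportion, in \[0, 1\].
#' @return Critical reputation loss (CNY/piece).
#' @export
critical_reputation_loss <- function(params, mode = c("given_y", "given_z"),
                                     proportion) {
  mode <- match.arg(mode)
  p <- unclass(validate_parameters(params))
  stopifnot(proportion >= 0, proportion <= 1)
  base <- p[["CG"]] + p[["GC"]] + p[["GH"]]
  if (mode == "given_y") base - p[["GC"]] * (1 - proportion)
  else base - (p[["GH"]] + p[["f1"]]) * (1 - proportion)
}

#' @rdname critical_reputation_loss
#' @return [regulation_dominant()]: `TRUE` when `H` exceeds the critical
#'   reputation loss, i.e. the corresponding indifference threshold
#'   exceeds 1 and regulation is evolutionarily favored for every value of
#'   the unobserved proportion.
#' @export
regulation_dominant <- function(params, mode = c("given_y", "given_z"),
                                proportion) {
  mode <- match.arg(mode)
  p <- unclass(validate_parameters(params))
  p[["H"]] > critical_reputation_loss(params, mode, proportion)
}

#' Midpoint region proportions
#'
#' The six summary proportions obtained by evaluating each population's
#' indifference condition with the relevant opponent proportion fixed at
#' one half: `v11`, `v12` (government regulation), `w21`, `w22`
#' (enterprises increasing production), `w31`, `w32` (institutions using
#' EFMs).  By construction `v11 = lambda_z(y = 1/2)` and
#' `v12 = lambda_y(z = 1/2)`; the `w` quantities are one minus the
#' corresponding indifference root.  The cost benefit `rc` enters `w31`
#' and `w32` positively (a larger reuse benefit raises adoption), as the
#' indifference derivation and the sensitivity table require;
#' `strict_print = TRUE` switches `v12`, `w31` and `w32` to the published
#' literal forms (which flip the `rc` sign) for audit.
#'
#' @param params a [game_parameters()] object.
#' @param strict_print use the published literal formulas for `v12`,
#'   `w31`, `w32` instead of the derivation-consistent defaults.
#' @param clip also return the proportions clipped to \[0, 1\].
#' @return A list with `v11, v12, w21, w22, w31, w32` (unclipped;
#'   values > 1 mean the regime holds everywhere) and, when
#'   `clip = TRUE`, a `clipped` sub-list.
#' @export
region_proportions <- function(params, strict_print = FALSE, clip = FALSE) {
  p <- unclass(validate_parameters(params))
  H <- p[["H"]]; f1 <- p[["f1"]]; f2 <- p[["f2"]]; CG <- p[["CG"]]
  GC <- p[["GC"]]; GH <- p[["GH"]]; CS <- p[["CS"]]; d <- p[["d"]]
  rc <- p[["rc"]]; aP <- p[["alpha"]] * p[["P"]]; bC <- p[["beta"]] * p[["C"]]
  P <- p[["P"]]
  if (GC == 0 || f1 + GH == 0 || aP == f2 || f2 == 0)
    stop("degenerate region proportions: need GC > 0, f1 + GH > 0, ",
         "alpha*P != f2, f2 > 0", call. = FALSE)
  v11 <- (2 * H + 2 * f1 - 2 * CG - GC) / (2 * f1 + 2 * GH)
  v12 <- if (strict_print) (2 * H + f1 - CG - GH) / (2 * GC)
         else (H + f1 - CG - (GH + f1) / 2) / GC
  w21 <- 1 - (f2 + 2 * bC + 2 * CS - 2 * P - aP) / (2 * GC)
  w22 <- 1 - (2 * bC + 2 * CS - GC - 2 * P) / (2 * aP - 2 * f2)
  rcs <- if (strict_print) -rc else rc  # published print has +2rc subtracted
  w31 <- 1 - (2 * aP + 2 * d - 2 * rcs + f2) / (2 * GH + 2 * f1)
  w32 <- 1 - (2 * aP + 2 * d - 2 * rcs + 2 * f2 - GH - f1) / (2 * f2)
  out <- list(v11 = v11, v12 = v12, w21 = w21, w22 = w22, w31 = w31,
              w32 = w32)
  if (clip)
    out$clipped <- lapply(out, function(v) min(max(v, 0), 1))
  out
}

# (quantity, parameter) pairs of the published sensitivity table, with the
# sign of the correlation column.
SENSITIVITY_ROWS <- data.frame(
  quantity = c("v11", "v11", "v11", "v12", "v12",
               "w21", "w21", "w21", "w21", "w21", "w22",
               "w31", "w31", "w31", "w31", "w32", "w32"),
  parameter = c("H", "CG", "GC", "GH", "f1",
                "f2", "beta", "CS", "alpha", "P", "GC",
                "alpha", "d", "rc", "f2", "GH", "f1"),
  expected_sign = c("+", "-", "-", "-", "+",
                    "-", "-", "-", "+", "+", "+",
                    "-", "-", "+", "-", "+", "+"),
  stringsAsFactors = FALSE
)

#' Sensitivity signs of the region proportions
#'
#' Central finite-difference partial derivatives of the six midpoint
#' region proportions with respect to each parameter in the published
#' sensitivity table, reduced to a sign.  At the baseline all 17 signs
#' match the published correlation column.
#'
#' @param params a [game_parameters()] object.
#' @param step relative perturbation for the central difference
#'   (default 1e-6).
#' @param pairs optional data frame with columns `quantity` and
#'   `parameter`; defaults to the published table's rows.
#' @return A data frame with columns `quantity`, `parameter`,
#'   `derivative`, `sign` (`"+"`, `"-"` or `"0"`) and, for default
#'   `pairs`, `expected_sign`.
#' @export
sensitivity_signs <- function(params, step = 1e-6, pairs = NULL) {
  stopifnot(step > 0)
  p <- unclass(validate_parameters(params))
  if (is.null(pairs)) pairs <- SENSITIVITY_ROWS
  eval_q <- function(pv, quantity) {
    pp <- pv
    class(pp) <- "game_parameters"
    region_proportions(pp)[[quantity]]
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    qty <- pairs$quantity[i]; par <- pairs$parameter[i]
    h <- step * max(abs(p[[par]]), 1)
    up <- p; up[[par]] <- up[[par]] + h
    dn <- p; dn[[par]] <- dn[[par]] - h
    der <- (eval_q(up, qty) - eval_q(dn, qty)) / (2 * h)
    sign_chr <- if (abs(der) < 1e-9) "0" else if (der > 0) "+" else "-"
    data.frame(quantity = qty, parameter = par, derivative = der,
               sign = sign_chr)
  })
  out <- do.call(rbind, res)
  if (!is.null(pairs$expected_sign)) out$expected_sign <- pairs$expected_sign
  out
}
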
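#' Pure-strategy payoff table
#'
#' Builds the eight-row payoff table of the tripartite game: one row per
#' combination of government action (regulate / deregulate), enterprise
#' action (increase / no_increase EFM production) and institution action
#' (efm / regular mask use), with the payoff of each player in CNY for a
#' run of `q` masks.
#'
#' The institution payoff in the (regulate, no_increase, efm) cell is
#' `(GH - alpha*P - d + rc - f2) q`: the liquidated damages `f2` are paid by
#' the institution (entering negatively), which is the form consistent with
#' the expected-utility expressions and the published eigenvalue table.
#'
#' @param params a [game_parameters()] object.
#' @return A data frame of class `payoff_table` with columns `government`,
#'   `enterprise`, `institution` (strategy labels) and `pay_government`,
#'   `pay_enterprise`, `pay_institution` (CNY).
#' @examples
#' pt <- payoff_table(game_parameters())
#' subset(pt, government == "regulate" & enterprise == "increase" &
#'            institution == "efm")
#' @export
payoff_table <- function(params) {
  p <- as.list(unclass(validate_parameters(params)))
  q <- p$q
  rows <- expand.grid(
    institution = c("efm", "regular"),
    enterprise = c("increase", "no_increase"),
    government = c("regulate", "deregulate"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("government", "enterprise", "institution")]

  pay <- with(p, {
    cell <- function(g, e, i) paste(g, e, i, sep = ".")
    m <- matrix(NA_real_, nrow = 8, ncol = 3,
                dimnames = list(NULL, c("gov", "ent", "inst")))
    key <- cell(rows$government, rows$enterprise, rows$institution)
    set <- function(k, gov, ent, inst) m[key == k, ] <<- c(gov, ent, inst) * q
    set("regulate.increase.efm",
        R - GC - GH - CG, alpha * P + GC - beta * C - CS,
        GH - alpha * P - d + rc)
    set("regulate.increase.regular",
        f1 - GC - CG, GC - beta * C - CS, -f1)
    set("regulate.no_increase.efm",
        R - GH - CG, f2 - P, GH - alpha * P - d + rc - f2)
    set("regulate.no_increase.regular",
        f1 - CG, 0, -f1)
    set("deregulate.increase.efm",
        R - H, alpha * P - beta * C - CS, -alpha * P - d + rc)
    set("deregulate.increase.regular",
        -H, -beta * C - CS, 0)
    set("deregulate.no_increase.efm",
        R - H, f2 - P, -alpha * P - d + rc - f2)
    set("deregulate.no_increase.regular",
        -H, 0, 0)
    m
  })
  out <- cbind(rows, data.frame(pay_government = pay[, "gov"],
                                pay_enterprise = pay[, "ent"],
                                pay_institution = pay[, "inst"]))
  class(out) <- c("payoff_table", "data.frame")
  out
}

# Look up one payoff cell as a named length-3 vector.
payoff_cell <- function(pt, government, enterprise, institution) {
  r <- pt[pt$government == government & pt$enterprise == enterprise &
            pt$institution == institution, ]
  c(government = r$pay_government, enterprise = r$pay_enterprise,
    institution = r$pay_institution)
}

PLAYERS <- c("government", "enterprise", "institution")

#' Expected utilities of a player
#'
#' Computes, from the payoff table, the expected payoff of the focal
#' ("adopt") action — regulate, increase production, or use EFMs — the
#' expected payoff of the alternative action, and the population mean
#' payoff, given the current strategy proportions of the other two
#' populations.
#'
#' @param params a [game_parameters()] object.
#' @param state a [strategy_state()] (or numeric `c(x, y, z)`).
#' @param player one of `"government"`, `"enterprise"`, `"institution"`.
#' @return A list with components `u_adopt`, `u_decline`, `u_mean` (CNY).
#'   `u_mean = s * u_adopt + (1 - s) * u_decline` where `s` is the player's
#'   own proportion.
#' @export
expected_utilities <- function(params, state, player) {
  player <- match.arg(player, PLAYERS)
  s <- as_strategy_state(state)
  pt <- payoff_table(params)
  x <- s[["x"]]; y <- s[["y"]]; z <- s[["z"]]

  # weight over the OTHER two populations' pure actions
  mix <- function(gov_w, ent_w, inst_w) {
    tot <- 0
    for (g in names(gov_w)) for (e in names(ent_w)) for (i in names(inst_w)) {
      w <- gov_w[[g]] * ent_w[[e]] * inst_w[[i]]
      if (w != 0) tot <- tot + w * payoff_cell(pt, g, e, i)[[player]]
    }
    tot
  }
  gw <- c(regulate = x, deregulate = 1 - x)
  ew <- c(increase = y, no_increase = 1 - y)
  iw <- c(efm = z, regular = 1 - z)
  if (player == "government") {
    u1 <- mix(c(regulate = 1), ew, iw)
    u2 <- mix(c(deregulate = 1), ew, iw)
    share <- x
  } else if (player == "enterprise") {
    u1 <- mix(gw, c(increase = 1), iw)
    u2 <- mix(gw, c(no_increase = 1), iw)
    share <- y
  } else {
    u1 <- mix(gw, ew, c(efm = 1))
    u2 <- mix(gw, ew, c(regular = 1))
    share <- z
  }
  list(u_adopt = u1, u_decline = u2,
       u_mean = share * u1 + (1 - share) * u2)
}

#' Payoff-table vs. replicator-equation consistency report
#'
#' For each player and supplied state, reports the residual between the
#' closed-form replicator rate and the rate `s(1-s)(U1 - U2)` recomputed
#' from the payoff table via [expected_utilities()].  Government and
#' institution residuals are zero to numerical precision.  The enterprise
#' equation in its published closed form carries an extra `y(1-y)(1-z)Pq`
#' relative to the payoff table (the `table2_consistent` variant removes
#' it); the residual is reported, never patched.
#'
#' @param params a [game_parameters()] object.
#' @param states a list of states (each a [strategy_state()] or numeric
#'   `c(x, y, z)`).
#' @param variant enterprise replicator variant, see [replicator_rate()].
#' @return A data frame with columns `state_id`, `x`, `y`, `z`, `player`,
#'   `rate_closed_form`, `rate_from_payoffs`, `residual`,
#'   `expected_residual` (the closed-form prediction `y(1-y)(1-z)Pq` for
#'   the enterprise under `as_printed`, 0 otherwise).
#' @export
payoff_consistency <- function(params, states,
                               variant = c("as_printed",
                                           "table2_consistent")) {
  variant <- match.arg(variant)
  if (!is.list(states) || length(states) == 0)
    stop("states must be a nonempty list", call. = FALSE)
  p <- unclass(validate_parameters(params))
  out <- list()
  for (i in seq_along(states)) {
    s <- as_strategy_state(states[[i]])
    for (player in PLAYERS) {
      u <- expected_utilities(params, s, player)
      share <- switch(player, government = s[["x"]], enterprise = s[["y"]],
                      institution = s[["z"]])
      from_pay <- share * (1 - share) * (u$u_adopt - u$u_decline)
      closed <- replicator_rate(params, s, player, variant)
      exp_res <- if (player == "enterprise" && variant == "as_printed") {
        s[["y"]] * (1 - s[["y"]]) * (1 - s[["z"]]) * p[["P"]] * p[["q"]]
      } else 0
      out[[length(out) + 1]] <- data.frame(
        state_id = i, x = s[["x"]], y = s[["y"]], z = s[["z"]],
        player = player, rate_closed_form = closed,
        rate_from_payoffs = from_pay, residual = closed - from_pay,
        expected_residual = exp_res)
    }
  }
  do.call(rbind, out)
}
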
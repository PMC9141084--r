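#' Replicator dynamics of the tripartite game
#'
#' The state (x, y, z) evolves by replicator dynamics: each population's
#' share of the focal strategy grows in proportion to that strategy's
#' payoff advantage over the population mean.  The closed-form rates are
#'
#' \deqn{dx/dt = x(1-x)(H + f_1 - C_G - z G_H - z f_1 - y G_C) q}
#' \deqn{dy/dt = y(1-y)(x G_C + z\alpha P - z f_2 + P - \beta C - C_S) q}
#' \deqn{dz/dt = z(1-z)(x G_H + x f_1 + y f_2 - \alpha P - d + r_c - f_2) q}
#'
#' The enterprise equation exists in two variants.  `as_printed` is the
#' published closed form above (the form behind the published eigenvalue
#' table).  `table2_consistent` replaces its `+P` with `+zP`, which is what
#' expanding the enterprise expected utilities from the payoff table
#' yields; the two differ by `y(1-y)(1-z)Pq` and coincide when `z = 1`.
#' See [payoff_consistency()].
#'
#' @param params a [game_parameters()] object.
#' @param state a [strategy_state()] or numeric `c(x, y, z)`.
#' @param player one of `"government"`, `"enterprise"`, `"institution"`.
#' @param variant `"as_printed"` (default) or `"table2_consistent"`.
#' @return [replicator_rate()]: a single rate (per unit time).
#'   [replicator_field()]: named numeric `c(x =, y =, z =)` with all three
#'   rates — the right-hand side of the ODE system.
#' @examples
#' replicator_field(game_parameters(), c(0.1, 0.1, 0.1))
#' @export
replicator_rate <- function(params, state, player,
                            variant = c("as_printed", "table2_consistent")) {
  player <- match.arg(player, PLAYERS)
  variant <- match.arg(variant)
  p <- unclass(validate_parameters(params))
  s <- as_strategy_state(state)
  share <- switch(player, government = s[["x"]], enterprise = s[["y"]],
                  institution = s[["z"]])
  share * (1 - share) * rate_factor(p, s, player, variant)
}

# The bracketed payoff-advantage factor (U1 - U2) of a player's rate;
# rate = share (1 - share) * factor.
rate_factor <- function(p, s, player, variant) {
  x <- s[["x"]]; y <- s[["y"]]; z <- s[["z"]]
  switch(player,
    government = (p[["H"]] + p[["f1"]] - p[["CG"]] - z * p[["GH"]] -
                    z * p[["f1"]] - y * p[["GC"]]) * p[["q"]],
    enterprise = {
      pterm <- if (variant == "as_printed") p[["P"]] else z * p[["P"]]
      (x * p[["GC"]] + z * p[["alpha"]] * p[["P"]] - z * p[["f2"]] +
         pterm - p[["beta"]] * p[["C"]] - p[["CS"]]) * p[["q"]]
    },
    institution = (x * p[["GH"]] + x * p[["f1"]] + y * p[["f2"]] -
                     p[["alpha"]] * p[["P"]] - p[["d"]] + p[["rc"]] -
                     p[["f2"]]) * p[["q"]]
  )
}

#' @rdname replicator_rate
#' @export
replicator_field <- function(params, state,
                             variant = c("as_printed", "table2_consistent")) {
  variant <- match.arg(variant)
  p <- unclass(validate_parameters(params))
  s <- as_strategy_state(state)
  c(x = s[["x"]] * (1 - s[["x"]]) * rate_factor(p, s, "government", variant),
    y = s[["y"]] * (1 - s[["y"]]) * rate_factor(p, s, "enterprise", variant),
    z = s[["z"]] * (1 - s[["z"]]) * rate_factor(p, s, "institution", variant))
}
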
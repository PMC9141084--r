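#' Exogenous game parameters
#'
#' Constructs and validates the set of fifteen exogenous constants that
#' parameterise the tripartite game between governments, mask enterprises
#' and medical institutions.  Monetary quantities are per mask (CNY/piece);
#' `alpha` and `beta` are dimensionless multipliers applied to the regular
#' mask price and cost; `q` is the number of environmentally friendly masks
#' (EFMs) in play.  Defaults are the packaged Chinese-mask-market baseline
#' (see [baseline_scenario()]).
#'
#' All fields must be non-negative except `rc`, the net per-mask cost
#' benefit of reuse, which is negative when cleaning/labour costs exceed the
#' savings from not repurchasing disposables.
#'
#' @param R environmental benefit of using EFMs (CNY/piece).
#' @param H reputation damage from government inaction (CNY/piece).
#' @param GC subsidy for producing EFMs (CNY/piece).
#' @param GH subsidy for using EFMs (CNY/piece).
#' @param P average price of a regular mask (CNY/piece).
#' @param C average cost of a regular mask (CNY/piece).
#' @param CG government regulation cost (CNY/piece).
#' @param CS EFM production machine transformation cost (CNY/piece).
#' @param d medical-institution management cost (CNY/piece).
#' @param rc cost benefit of using EFMs (CNY/piece); may be negative.
#' @param f1 environmental penalty on institutions not using EFMs (CNY/piece).
#' @param f2 liquidated damages for terminating regular-mask purchase
#'   contracts (CNY/piece).
#' @param q number of EFMs used (pieces, > 0).
#' @param alpha price increase coefficient of EFMs (> 0).
#' @param beta cost increase coefficient of EFMs (> 0).
#' @return An object of class `game_parameters`: a named numeric vector with
#'   the fifteen fields above.
#' @examples
#' p <- game_parameters()        # baseline
#' p2 <- game_parameters(rc = -2) # costly reuse
#' @export
game_parameters <- function(R = 0.8, H = 1.8, GC = 2, GH = 0.2, P = 1,
                            C = 0.5, CG = 0.05, CS = 0.3, d = 0.05, rc = 2,
                            f1 = 0.1, f2 = 0.2, q = 1, alpha = 1.5,
                            beta = 1.5) {
  p <- c(R = R, H = H, GC = GC, GH = GH, P = P, C = C, CG = CG, CS = CS,
         d = d, rc = rc, f1 = f1, f2 = f2, q = q, alpha = alpha, beta = beta)
  class(p) <- "game_parameters"
  validate_parameters(p)
  p
}

#' @rdname game_parameters
#' @param x object to test or validate.
#' @export
is_game_parameters <- function(x) inherits(x, "game_parameters")

PARAMETER_FIELDS <- c("R", "H", "GC", "GH", "P", "C", "CG", "CS", "d", "rc",
                      "f1", "f2", "q", "alpha", "beta")

#' Validate a parameter set
#'
#' Checks completeness, finiteness and the sign rules: `q > 0`,
#' `alpha > 0`, `beta > 0`, every other field non-negative except `rc`,
#' which alone may be negative.
#'
#' @param p a `game_parameters` object or named numeric vector.
#' @return `p`, invisibly, after coercion to `game_parameters`; errors name
#'   the offending field.
#' @export
validate_parameters <- function(p) {
  v <- unclass(p)
  missing <- setdiff(PARAMETER_FIELDS, names(v))
  if (length(missing) > 0)
    stop("missing parameter field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(v), PARAMETER_FIELDS)
  if (length(extra) > 0)
    stop("unknown parameter field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  v <- v[PARAMETER_FIELDS]
  if (!is.numeric(v) || any(!is.finite(v)))
    stop("all parameter fields must be finite numbers", call. = FALSE)
  nonneg <- setdiff(PARAMETER_FIELDS, c("rc", "q", "alpha", "beta"))
  bad <- nonneg[v[nonneg] < 0]
  if (length(bad) > 0)
    stop("parameter(s) must be non-negative: ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (f in c("q", "alpha", "beta"))
    if (v[[f]] <= 0) stop("parameter must be positive: ", f, call. = FALSE)
  out <- v
  class(out) <- "game_parameters"
  invisible(out)
}

#' @export
print.game_parameters <- function(x, ...) {
  cat("Tripartite game parameters (CNY/piece unless noted):\n")
  print(round(unclass(x), 6))
  invisible(x)
}

#' Strategy state of the three populations
#'
#' A point in the unit cube giving the proportion of governments that
#' regulate (`x`), of enterprises that increase EFM production (`y`), and
#' of medical institutions that use EFMs (`z`).
#'
#' @param x,y,z proportions in \[0, 1\].
#' @return Named numeric vector of class `strategy_state`.
#' @export
strategy_state <- function(x, y, z) {
  s <- c(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1))
    stop("strategy proportions must lie in [0, 1]", call. = FALSE)
  class(s) <- "strategy_state"
  s
}

# Accepts a strategy_state or a bare length-3 numeric (x, y, z).
as_strategy_state <- function(s) {
  if (inherits(s, "strategy_state")) return(s)
  if (is.numeric(s) && length(s) == 3) return(strategy_state(s[1], s[2], s[3]))
  stop("expected a strategy_state or a numeric vector (x, y, z)",
       call. = FALSE)
}

#' Read or write a parameter file
#'
#' Parameter files are flat key–value documents with exactly the fifteen
#' field names of [game_parameters()].  JSON is read with jsonlite; files
#' ending in `.yaml`/`.yml` are read with a minimal flat `key: value`
#' parser (nested YAML is not supported).  Unknown keys are an error.
#'
#' @param path file path; format chosen by extension (`.json`, `.yaml`,
#'   `.yml`).
#' @return [read_parameters()] returns a validated `game_parameters`
#'   object; [write_parameters()] returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("no such parameter file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") {
    unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  } else if (ext %in% c("yaml", "yml")) {
    read_flat_yaml(path)
  } else stop("unsupported parameter file extension: .", ext, call. = FALSE)
  p <- validate_parameters(vals)
  p
}

#' @rdname read_parameters
#' @param p a `game_parameters` object.
#' @export
write_parameters <- function(p, path) {
  p <- validate_parameters(p)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(as.list(unclass(p)), path, auto_unbox = TRUE,
                         digits = NA)
  } else if (ext %in% c("yaml", "yml")) {
    writeLines(sprintf("%s: %.17g", names(unclass(p)), unclass(p)), path)
  } else stop("unsupported parameter file extension: .", ext, call. = FALSE)
  invisible(path)
}

# Flat "key: value" reader; comments (#) and blank lines allowed.
read_flat_yaml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(\\S+)$", lines))
  bad <- lines[vapply(kv, length, 1L) != 3]
  if (length(bad) > 0)
    stop("cannot parse flat YAML line(s): ", paste(bad, collapse = "; "),
         call. = FALSE)
  vals <- as.numeric(vapply(kv, `[`, "", 3))
  names(vals) <- vapply(kv, `[`, "", 2)
  if (any(is.na(vals)))
    stop("non-numeric value in parameter file", call. = FALSE)
  vals
}

#' Path of the packaged baseline parameter file
#'
#' The JSON file shipped under `inst/extdata/` reproducing the baseline
#' calibration bit-exactly.
#'
#' @return Absolute path to `baseline_params.json`.
#' @export
baseline_parameter_file <- function() {
  system.file("extdata", "baseline_params.json", package = "greengame",
              mustWork = TRUE)
}
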
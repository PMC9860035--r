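#' Game and institution parameters
#'
#' Bundles the six scalar parameters of the public-goods game with monitoring
#' and punishment: group size, public-goods efficiency, monitoring efficiency,
#' punishment efficiency, the contribution threshold, and the punishment
#' reserve.
#'
#' @param N Integer group size (number of individuals/nodes), `N >= 2`.
#' @param b Public-goods efficiency: contributions to the public good are
#'   multiplied by `b` (`b >= 1`) and shared equally among the *other*
#'   `N - 1` individuals.
#' @param m Monitoring efficiency (`m > 0`): one unit of resource effectively
#'   monitors `m` individuals, i.e. monitoring one individual costs `1/m`.
#' @param p Punishment efficiency (`p > 0`): each unit a punisher spends
#'   removes `p` units from the punished individual's payoff.
#' @param c_t Contribution threshold (`c_t > 0`): the total amount a
#'   contributor pays across monitoring, punishment, and the public good.
#' @param c_p Punishment reserve (`0 < c_p <= c_t`): the amount any individual
#'   with monitoring responsibilities holds back to punish free-riders they
#'   monitor.
#'
#' @return An object of class `game_params`: a named list with the six fields.
#' @examples
#' game_params(N = 6, b = 2, m = 4, p = 1, c_t = 1, c_p = 0.2)
#' @export
game_params <- function(N, b, m, p, c_t, c_p) {
  stopifnot(
    "N must be a single integer >= 2" =
      length(N) == 1 && is.finite(N) && N >= 2 && N == as.integer(N),
    "b must be a single number >= 1" = length(b) == 1 && is.finite(b) && b >= 1,
    "m must be a single positive number" = length(m) == 1 && is.finite(m) && m > 0,
    "p must be a single positive number" = length(p) == 1 && is.finite(p) && p > 0,
    "c_t must be a single positive number" =
      length(c_t) == 1 && is.finite(c_t) && c_t > 0,
    "c_p must satisfy 0 < c_p <= c_t" =
      length(c_p) == 1 && is.finite(c_p) && c_p > 0 && c_p <= c_t
  )
  structure(
    list(N = as.integer(N), b = b, m = m, p = p, c_t = c_t, c_p = c_p),
    class = "game_params"
  )
}

#' @export
print.game_params <- function(x, ...) {
  cat("<game_params>\n")
  cat(sprintf("  N = %d individuals\n", x$N))
  cat(sprintf("  b = %g (public-goods efficiency)\n", x$b))
  cat(sprintf("  m = %g (monitoring efficiency)\n", x$m))
  cat(sprintf("  p = %g (punishment efficiency)\n", x$p))
  cat(sprintf("  c_t = %g (contribution threshold)\n", x$c_t))
  cat(sprintf("  c_p = %g (punishment reserve)\n", x$c_p))
  invisible(x)
}

#' Read or write game parameters as JSON or YAML
#'
#' Parameters are stored as a flat mapping with keys
#' `N, b, m, p, c_t, c_p`. The format is inferred from the file
#' extension (`.json`, `.yaml`, `.yml`).
#'
#' @param path File path.
#' @return `read_game_params()` returns a [game_params] object;
#'   `write_game_params()` returns `path` invisibly.
#' @export
read_game_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("Unsupported parameter file extension: ", ext, call. = FALSE)
  )
  needed <- c("N", "b", "m", "p", "c_t", "c_p")
  missing <- setdiff(needed, names(vals))
  if (length(missing) > 0) {
    stop("Parameter file missing fields: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  do.call(game_params, vals[needed])
}

#' @rdname read_game_params
#' @param params A [game_params] object.
#' @export
write_game_params <- function(params, path) {
  stopifnot(inherits(params, "game_params"))
  ext <- tolower(tools::file_ext(path))
  x <- unclass(params)
  switch(ext,
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml = yaml::write_yaml(x, path),
    stop("Unsupported parameter file extension: ", ext, call. = FALSE)
  )
  invisible(path)
}
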
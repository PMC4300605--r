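#' @importFrom rlang abort %||%
#' @importFrom dplyr filter mutate select arrange bind_rows distinct left_join group_by summarise ungroup pull rename n
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_lgl map_dbl map2 pmap
NULL

# Classed condition helpers: every user-facing error carries class
# "fluxmapr_error" plus a specific subclass so callers (and the CLI) can
# distinguish user errors from internal ones.
stop_fluxmapr <- function(message, class, ...) {
  abort(message, class = c(paste0("fluxmapr_", class, "_error"), "fluxmapr_error"), ...)
}

stop_not_found <- function(id, what = "node") {
  stop_fluxmapr(sprintf("%s '%s' not found in layout", what, id), "not_found")
}

stop_wrong_kind <- function(id, expected) {
  stop_fluxmapr(sprintf("node '%s' is not a %s node", id, expected), "wrong_kind")
}

stop_argument <- function(message) stop_fluxmapr(message, "argument")
stop_parse <- function(message) stop_fluxmapr(message, "parse")
stop_format <- function(message) stop_fluxmapr(message, "format")
stop_unsupported <- function(message) stop_fluxmapr(message, "unsupported")

# Character-vector set equality (order- and duplication-insensitive).
setequal_chr <- function(a, b) setequal(as.character(a), as.character(b))

# Stable key for an edge triple.
edge_key <- function(reaction_id, metabolite_id, role) {
  paste(reaction_id, metabolite_id, role, sep = "\r")
}

# Format a flux value for node labels: fixed-point, no scientific notation.
format_flux <- function(x, decimals = 3) {
  formatC(x, format = "f", digits = decimals)
}

# Linear interpolation between two colours in RGB space, weight w in [0, 1]
# pulling from `from` toward `to`.
blend_color <- function(from, to, w) {
  n <- max(length(to), length(w))
  if (n == 0) return(character())
  to <- rep(to, length.out = n)
  w <- rep(w, length.out = n)
  f <- grDevices::col2rgb(from)[, 1]
  t <- grDevices::col2rgb(to)
  wm <- matrix(rep(w, each = 3), nrow = 3)
  m <- round(f + wm * (t - f))
  grDevices::rgb(m[1, ], m[2, ], m[3, ], maxColorValue = 255)
}
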
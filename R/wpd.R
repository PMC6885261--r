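## Wavelet packet decomposition: periodized orthogonal filter bank.
##
## Scaling (low-pass) filters h in natural order; the quadrature mirror
## high-pass is g[n] = (-1)^n h[L-1-n]. With periodic (circular) extension and
## dyadic downsampling the analysis operator is exactly orthogonal for every
## even signal length, which gives machine-precision Parseval and perfect
## reconstruction — the two invariants the feature extractor relies on.

# Scaling filter coefficients (sum = sqrt(2)); full double precision.
WPD_FILTERS <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314453416, 0.8365163037378079,
          0.2241438680420134, -0.12940952255126037),
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.0328830116668852, -0.010597401785069032),
  db8 = c(0.05441584224310401, 0.31287159091429995, 0.6756307362972898,
          0.5853546836542067, -0.015829105256349306, -0.2840155429615469,
          0.0004724845739132828, 0.12874742662047847, -0.017369301001807547,
          -0.044088253930794755, 0.013981027917398282, 0.008746094047405777,
          -0.004870352993451574, -0.00039174037337694705,
          0.0006754494064505693, -0.00011747678412476953),
  sym4 = c(0.0322231006040427, -0.012603967262037833, -0.09921954357684722,
           0.29785779560527736, 0.8037387518059161, 0.49761866763201545,
           -0.02963552764599851, -0.07576571478927333),
  sym8 = c(0.0018899503327594609, -0.0003029205147213668, -0.01495225833704823,
           0.003808752013890615, 0.049137179673607506, -0.027219029917056003,
           -0.05194583810770904, 0.3644418948353314, 0.7771857517005235,
           0.4813596512583722, -0.061273359067658524, -0.1432942383508097,
           0.007607487324917605, 0.03169508781149298, -0.0005421323317911481,
           -0.0033824159510061256)
)

#' Orthogonal wavelet filter pair
#'
#' Looks up the scaling (low-pass) filter for a named orthogonal wavelet and
#' derives the quadrature-mirror high-pass filter.
#'
#' @param wavelet_name One of `"haar"` (alias `"db1"`), `"db2"`, `"db4"`,
#'   `"db8"`, `"sym4"`, `"sym8"`.
#' @return List with elements `lo` and `hi` (numeric filter taps) and `name`.
#' @export
wpd_filters <- function(wavelet_name) {
  name <- if (identical(wavelet_name, "db1")) "haar" else wavelet_name
  h <- WPD_FILTERS[[name]]
  if (is.null(h)) {
    stop("unknown wavelet '", wavelet_name, "'; available: ",
         paste(c(names(WPD_FILTERS), "db1"), collapse = ", "), call. = FALSE)
  }
  L <- length(h)
  g <- (-1)^(0:(L - 1L)) * rev(h)
  list(name = name, lo = h, hi = g)
}

#' Wavelet packet decomposition configuration
#'
#' @param wavelet_name Orthogonal wavelet (default `"db4"`).
#' @param level Decomposition depth (default 4; the terminal level then holds
#'   `2^level` uniform subbands).
#' @param extension_mode Boundary handling; only `"periodic"` is implemented
#'   (the orthogonal mode that preserves energy and coefficient counts).
#' @param subband_set `"terminal"` (the `2^level` deepest nodes, default) or
#'   `"all_nodes"` (every node of every level, `2^(level+1) - 2` subbands).
#' @param ordering `"frequency"` (Gray-code sequency order, default) or
#'   `"natural"` (filter-bank order).
#' @return Object of class `wpd_config`.
#' @export
wpd_config <- function(wavelet_name = "db4", level = 4L,
                       extension_mode = c("periodic", "symmetric", "zero"),
                       subband_set = c("terminal", "all_nodes"),
                       ordering = c("frequency", "natural")) {
  extension_mode <- match.arg(extension_mode)
  if (extension_mode != "periodic") {
    stop("extension_mode '", extension_mode, "' is not implemented; ",
         "use 'periodic'", call. = FALSE)
  }
  level <- as.integer(level)
  if (level < 1L) stop("level must be >= 1", call. = FALSE)
  filters <- wpd_filters(wavelet_name)  # validates the name
  structure(list(wavelet_name = filters$name, level = level,
                 extension_mode = extension_mode,
                 subband_set = match.arg(subband_set),
                 ordering = match.arg(ordering)),
            class = "wpd_config")
}

# One analysis step: circular filtering + dyadic downsampling.
# a[k] = sum_l h[l] x[(2k + l) mod N], same for the high-pass branch.
wpd_analysis_step <- function(x, filters) {
  N <- length(x)
  K <- N %/% 2L
  base <- 2L * (0:(K - 1L))
  a <- numeric(K)
  d <- numeric(K)
  for (l in seq_along(filters$lo)) {
    idx <- (base + (l - 1L)) %% N + 1L
    xl <- x[idx]
    a <- a + filters$lo[l] * xl
    d <- d + filters$hi[l] * xl
  }
  list(a = a, d = d)
}

# Inverse of wpd_analysis_step (adjoint of the orthogonal operator).
wpd_synthesis_step <- function(a, d, filters) {
  K <- length(a)
  N <- 2L * K
  x <- numeric(N)
  base <- 2L * (0:(K - 1L))
  for (l in seq_along(filters$lo)) {
    idx <- (base + (l - 1L)) %% N + 1L
    x[idx] <- x[idx] + filters$lo[l] * a + filters$hi[l] * d
  }
  x
}

# Terminal-node paths of a level-`level` packet tree in the requested order.
# Frequency (sequency) order follows the aliasing rule: a node whose path
# contains an even number of 'd' steps expands low-then-high, otherwise
# high-then-low (downsampling mirrors the spectrum of the detail branch).
wpd_node_paths <- function(level, ordering = c("frequency", "natural")) {
  ordering <- match.arg(ordering)
  paths <- ""
  for (lev in seq_len(level)) {
    paths <- unlist(lapply(paths, function(p) {
      if (ordering == "natural" ||
          sum(strsplit(p, "")[[1]] == "d") %% 2L == 0L) {
        c(paste0(p, "a"), paste0(p, "d"))
      } else {
        c(paste0(p, "d"), paste0(p, "a"))
      }
    }))
  }
  paths
}

#' Decompose a frame into wavelet packet subbands
#'
#' Runs the full packet tree down to `config$level` and returns the subband
#' coefficient blocks in the configured ordering. With the default periodic
#' mode and an orthogonal wavelet the transform is energy preserving: the sum
#' of squared coefficients over the terminal subbands equals the sum of
#' squared frame samples to machine precision.
#'
#' @param frame Numeric vector; length must be divisible by `2^level`.
#' @param config A [wpd_config()].
#' @return List of subbands, each a list with `level`, `index` (0-based
#'   position within its level under the configured ordering), `path`
#'   (a/d steps from the root), and `coefficients`.
#' @export
wpd_decompose <- function(frame, config = wpd_config()) {
  stopifnot(inherits(config, "wpd_config"))
  if (!is.numeric(frame) || any(!is.finite(frame))) {
    stop("frame must be a finite numeric vector", call. = FALSE)
  }
  n <- length(frame)
  if (n %% 2^config$level != 0L || n < 2^config$level) {
    stop("frame length ", n, " is not divisible by 2^level = ",
         2^config$level, call. = FALSE)
  }
  filters <- wpd_filters(config$wavelet_name)
  # nodes[[path]] holds the coefficient block for that a/d path
  nodes <- list()
  nodes[[1L]] <- frame
  names(nodes) <- ""
  all_levels <- list()
  for (lev in seq_len(config$level)) {
    nxt <- list()
    for (pi in seq_along(nodes)) {
      p <- names(nodes)[pi]
      st <- wpd_analysis_step(nodes[[pi]], filters)
      nxt[[paste0(p, "a")]] <- st$a
      nxt[[paste0(p, "d")]] <- st$d
    }
    nodes <- nxt
    all_levels[[lev]] <- nodes
  }
  levels_wanted <- if (config$subband_set == "terminal") config$level else
    seq_len(config$level)
  out <- list()
  for (lev in levels_wanted) {
    paths <- wpd_node_paths(lev, config$ordering)
    for (i in seq_along(paths)) {
      out[[length(out) + 1L]] <- list(
        level = lev, index = i - 1L, path = paths[i],
        coefficients = all_levels[[lev]][[paths[i]]])
    }
  }
  out
}

#' Reconstruct a frame from its terminal wavelet packet subbands
#'
#' Inverts [wpd_decompose()] from a complete terminal subband set. Perfect
#' reconstruction holds to machine precision.
#'
#' @param subbands List of subbands as returned by [wpd_decompose()] (terminal
#'   nodes of `config$level`; extra shallower nodes are ignored).
#' @param config The [wpd_config()] used to decompose.
#' @return Numeric vector, the reconstructed frame.
#' @export
wpd_reconstruct <- function(subbands, config = wpd_config()) {
  stopifnot(inherits(config, "wpd_config"))
  filters <- wpd_filters(config$wavelet_name)
  terminal <- subbands[vapply(subbands, function(s) s$level == config$level,
                              logical(1))]
  expected <- wpd_node_paths(config$level, "natural")
  have <- vapply(terminal, `[[`, character(1), "path")
  missing <- setdiff(expected, have)
  if (length(missing) > 0L) {
    stop("incomplete terminal subband set: missing node(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  nodes <- lapply(terminal, `[[`, "coefficients")
  names(nodes) <- have
  for (lev in rev(seq_len(config$level))) {
    parents <- unique(substr(names(nodes), 1L, lev - 1L))
    if (lev == 1L) parents <- ""
    nxt <- list()
    for (p in parents) {
      nxt[[if (nzchar(p)) p else 1L]] <-
        wpd_synthesis_step(nodes[[paste0(p, "a")]], nodes[[paste0(p, "d")]],
                           filters)
    }
    if (lev == 1L) {
      return(nxt[[1L]])
    }
    names(nxt) <- parents
    nodes <- nxt
  }
}
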
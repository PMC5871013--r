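#' Piecewise population-size history
#'
#' A demography is an ordered list of epochs, earliest first, each either a
#' constant-size epoch (`list(gens = , N = )`) or an exponential epoch
#' (`list(gens = , N_start = , N_end = , mode = "exp")`) discretized per
#' generation (sizes rounded to the nearest integer, floored at 2). The final
#' generation of the last epoch is "the present".
#'
#' @param epochs list of epoch specs as above.
#' @return Object of class `demography`: list with `epochs` and `N` (integer
#'   vector of diploid sizes per generation, oldest first).
#' @examples
#' d <- demography(list(list(gens = 1000, N = 5000),
#'                      list(gens = 100, N_start = 5000, N_end = 50000,
#'                           mode = "exp")))
#' length(d$N)  # 1100
#' @export
demography <- function(epochs) {
  if (!is.list(epochs) || !length(epochs)) stop("'epochs' must be a non-empty list")
  Nv <- lapply(epochs, function(e) {
    if (is.null(e$gens) || e$gens < 1) stop("each epoch needs gens >= 1")
    g <- as.integer(e$gens)
    if (!is.null(e$mode) && identical(e$mode, "exp")) {
      if (is.null(e$N_start) || is.null(e$N_end))
        stop("exponential epoch needs N_start and N_end")
      if (e$N_start < 2 || e$N_end < 2) stop("population sizes must be >= 2")
      pmax(2L, as.integer(round(e$N_start *
        (e$N_end / e$N_start)^(seq_len(g) / g))))
    } else {
      if (is.null(e$N)) stop("constant epoch needs N")
      if (e$N < 2) stop("population sizes must be >= 2")
      rep(as.integer(e$N), g)
    }
  })
  structure(list(epochs = epochs, N = unlist(Nv)), class = "demography")
}

#' Constant-size demography
#'
#' @param N diploid population size.
#' @param gens number of generations.
#' @return A [demography()] object with a single constant epoch.
#' @export
demography_constant <- function(N, gens) {
  demography(list(list(gens = gens, N = N)))
}

#' @export
print.demography <- function(x, ...) {
  cat(sprintf("demography: %d epochs, %d generations, N range [%d, %d]\n",
              length(x$epochs), length(x$N), min(x$N), max(x$N)))
  for (e in x$epochs) {
    if (!is.null(e$mode) && identical(e$mode, "exp"))
      cat(sprintf("  %6d gens: exponential %d -> %d\n",
                  as.integer(e$gens), as.integer(e$N_start), as.integer(e$N_end)))
    else
      cat(sprintf("  %6d gens: constant N = %d\n",
                  as.integer(e$gens), as.integer(e$N)))
  }
  invisible(x)
}

#' Read a demography from a YAML or JSON file
#'
#' Expected layout: a top-level `epochs` sequence, each entry with `gens` and
#' either `N` or (`N_start`, `N_end`, `mode: exp`), e.g.
#' `epochs: [{gens: 1500, N: 2000}, {gens: 200, N_start: 2000, N_end: 100000, mode: exp}]`.
#'
#' @param path file path (`.json` parsed as JSON, otherwise YAML).
#' @return A [demography()] object.
#' @export
read_demography <- function(path) {
  if (!file.exists(path)) stop("demography file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE) else .read_yaml_cfg(path)
  if (is.null(cfg$epochs)) stop("demography file must have an 'epochs' list")
  demography(cfg$epochs)
}
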
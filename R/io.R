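# Readers and writers for GWAS hit tables (plain TSV with a comment header
# carrying provenance) and small JSON fit summaries. Frequencies in storage
# are always frequencies of the effect allele in (0,1); MAF folding happens
# only inside statistics.

# YAML 1.1 resolves bare n/N/y/yes/no as booleans, clobbering the model's key
# names; these handlers keep the original strings
.read_yaml_cfg <- function(path) {
  yaml::yaml.load(paste(readLines(path), collapse = "\n"),
                  handlers = list("bool#yes" = function(x) x,
                                  "bool#no" = function(x) x))
}

#' Read a GWAS hit table from TSV
#'
#' Expects a tab-separated file with a header naming at least `snp`, `freq`
#' and either `beta` or `var_explained` (optional: `n`). Lines starting with
#' `#` are ignored. Rows with missing or out-of-range values (`freq` outside
#' (0,1), non-finite effect) are dropped and counted in a message.
#'
#' @param path file path.
#' @param compute_var if TRUE (default) fill `var_explained = 2 beta^2 p q`
#'   where absent.
#' @return data.frame with attribute `n_dropped`.
#' @export
read_gwas_tsv <- function(path, compute_var = TRUE) {
  if (!file.exists(path)) stop("GWAS file not found: ", path)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("snp", "freq")
  miss <- setdiff(need, names(tab))
  if (!("beta" %in% names(tab)) && !("var_explained" %in% names(tab)))
    miss <- c(miss, "beta|var_explained")
  if (length(miss))
    stop("GWAS table is missing required columns: ", paste(miss, collapse = ", "))
  n0 <- nrow(tab)
  ok <- is.finite(tab$freq) & tab$freq > 0 & tab$freq < 1
  if (!is.null(tab$beta)) ok <- ok & is.finite(tab$beta)
  if (!is.null(tab$var_explained))
    ok <- ok & is.finite(tab$var_explained) & tab$var_explained >= 0
  tab <- tab[ok, , drop = FALSE]
  dropped <- n0 - nrow(tab)
  if (dropped > 0)
    message(dropped, " row(s) dropped (invalid frequency or effect)")
  if (compute_var && is.null(tab$var_explained) && !is.null(tab$beta))
    tab$var_explained <- 2 * tab$beta^2 * tab$freq * (1 - tab$freq)
  attr(tab, "n_dropped") <- dropped
  tab
}

#' Write a GWAS hit table to TSV with a provenance header
#'
#' @param tab data.frame (e.g. from [generate_gwas_table()]).
#' @param path output path.
#' @param seed optional seed to record in the header.
#' @param extra named character vector of extra header fields.
#' @return `path`, invisibly.
#' @export
write_gwas_tsv <- function(tab, path, seed = attr(tab, "seed"), extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stabarch %s",
                     as.character(utils::packageVersion("stabarch"))), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", seed), con)
  if (!is.null(attr(tab, "v_star")))
    writeLines(sprintf("# v_star: %.10g", attr(tab, "v_star")), con)
  for (nm in names(extra)) writeLines(sprintf("# %s: %s", nm, extra[[nm]]), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a fit result to JSON
#'
#' @param fit a [fit_vs()] object.
#' @param path output path.
#' @param target optional [estimate_target_size()] result to include.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, target = NULL) {
  stopifnot(inherits(fit, "vs_fit"))
  out <- list(vs = fit$vs, v_star = fit$v_star, mode = fit$mode,
              weighting = fit$weighting, n_loci = fit$n_loci,
              logLik = fit$logLik, ci = fit$ci,
              version = as.character(utils::packageVersion("stabarch")))
  if (!is.null(target))
    out$target <- list(L_detectable = target$L_detectable,
                       L_mb = target$L_mb,
                       detectable_fraction = target$detectable_fraction,
                       ci_L = target$ci_L)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
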
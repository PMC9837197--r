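#' Read a rectangular numeric CSV with missing-value tokens
#'
#' Both the string `"NA"` and the empty field are recognized as missing.
#'
#' @param path file path.
#' @param missing_token additional token treated as missing.
#' @return a numeric matrix with `NA` for missing cells (validated by
#'   [incomplete_data()] when any column is observed).
#' @export
read_csv_missing <- function(path, missing_token = "NA") {
  df <- utils::read.csv(path, na.strings = unique(c(missing_token, "NA", "")),
                        check.names = FALSE)
  X <- as.matrix(df)
  if (!is.numeric(X)) stop("non-numeric observed cells in ", path)
  X
}

#' Write a numeric matrix as CSV with "NA" for missing cells
#'
#' Round-trips with [read_csv_missing()].
#'
#' @param x numeric matrix or data frame.
#' @param path file path.
#' @export
write_csv_missing <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a prior specification file
#'
#' YAML with keys `mu0` (list), `tau`, `m`, `Lambda` (list of rows) and
#' optionally `convention`.
#'
#' @param path file path.
#' @return a [niw_prior()].
#' @export
read_prior_file <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("mu0", "tau", "m", "Lambda")
  if (!all(need %in% names(y)))
    stop("prior file must provide: ", paste(need, collapse = ", "))
  Lambda <- do.call(rbind, lapply(y$Lambda, as.numeric))
  conv <- if (is.null(y$convention)) "scale_literal" else y$convention
  niw_prior(mu0 = as.numeric(y$mu0), tau = y$tau, m = y$m, Lambda = Lambda,
            convention = conv)
}

#' Write a conditional NIG prior in the flat key-value format
#'
#' @param prior a [nig_prior()].
#' @param path file path, or `""` to print to the console.
#' @export
write_nig_file <- function(prior, path = "") {
  stopifnot(inherits(prior, "nig_prior"))
  out <- list(sigma_df = prior$sigma_df, sigma_scale = prior$sigma_scale,
              coef_mean = as.numeric(prior$coef_mean),
              coef_scale = lapply(seq_len(nrow(prior$coef_scale)),
                                  function(i) as.numeric(prior$coef_scale[i, ])))
  txt <- yaml::as.yaml(out)
  if (identical(path, "")) cat(txt) else writeLines(txt, path)
  invisible(path)
}
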
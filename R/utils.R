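#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cutree dhyper hclust as.dist dist pf p.adjust
#'   chisq.test rbinom rnorm runif sd
#' @importFrom utils read.delim
NULL

#' The five intrinsic breast-cancer subtype labels
#'
#' Default subtype vocabulary used throughout the pipeline: luminal A,
#' luminal B, HER2-enriched, basal-like and normal-like.
#'
#' @format character vector of length 5.
#' @export
PAM50_SUBTYPES <- c("LumA", "LumB", "Her2", "Basal", "Normal")

stop2 <- function(...) stop(..., call. = FALSE)

check_scalar_int <- function(x, name, min = NULL) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x))
    stop2(sprintf("`%s` must be a single integer", name))
  if (!is.null(min) && x < min)
    stop2(sprintf("`%s` must be >= %s (got %s)", name, min, x))
  as.integer(x)
}

check_scalar_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop2(sprintf("`%s` must be a single finite number", name))
  if (x < min || x > max)
    stop2(sprintf("`%s` must be in [%s, %s] (got %s)", name, min, max, x))
  as.numeric(x)
}

#' Order chromosome names naturally
#'
#' Numeric chromosome names sort numerically ("2" before "10"); non-numeric
#' names (e.g. "X") follow, alphabetically.
#'
#' @param chrom character vector of chromosome names.
#' @return an integer ranking usable as a sort key.
#' @export
chrom_order <- function(chrom) {
  chrom <- as.character(chrom)
  num <- suppressWarnings(as.numeric(chrom))
  key <- ifelse(is.na(num), Inf, num)
  order(key, chrom)
}

# 10-significant-digit serialization used by all writers so that re-runs
# are byte-identical.
fmt_num <- function(x) {
  out <- sprintf("%.10g", x)
  out[is.na(x)] <- "NA"
  out
}

write_tsv_lines <- function(df, path) {
  cells <- lapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  })
  body <- do.call(paste, c(cells, sep = "\t"))
  writeLines(c(paste(names(df), collapse = "\t"), body), path)
}
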
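# Shared helpers: seed streams, table IO, small statistical utilities.

#' Derive a reproducible sub-seed for a named pipeline stage
#'
#' Every stochastic stage draws its seed from the run seed plus the stage
#' name, so stages can be rerun independently without sharing RNG state.
#'
#' @param seed Integer run seed.
#' @param stage Character stage name.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% (.Machine$integer.max - 1L) + 1)
}

#' Read a numeric matrix from TSV (first column = row identifiers)
#' @param path File path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a matrix to TSV with a leading identifier column
#' @param m Matrix with rownames.
#' @param path Output path.
#' @param id_name Name for the identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Odds ratio of a 2x2 table (a,b,c,d row-wise). A genuinely infinite ratio
# (zero off-diagonal with non-zero diagonal) is reported as the cap
# sentinel; other zero-cell tables get the Haldane 0.5 correction.
odds_ratio <- function(a, b, c, d, cap = 1e6) {
  if (b * c == 0 && a * d > 0) return(cap)
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  min((a * d) / (b * c), cap)
}

# One-tailed (enrichment) Fisher p via the hypergeometric tail:
# P(X >= overlap) with `fg` draws from `n_cat` marked out of `n_universe`.
hyper_p <- function(overlap, n_fg, n_cat, n_universe) {
  phyper(overlap - 1, n_cat, n_universe - n_cat, n_fg, lower.tail = FALSE)
}

# Internal assertion with a readable message.
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
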
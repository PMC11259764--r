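# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' SHA-256 hex digest of a character scalar or vector
#'
#' Thin vectorised wrapper around [openssl::sha256()] returning lowercase hex.
#' Used for identity hashing and ledger block hashes.
#'
#' @param x character vector.
#' @return character vector of 64-char lowercase hex digests.
#' @keywords internal
sha256_hex <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) as.character(openssl::sha256(s)), character(1),
         USE.NAMES = FALSE)
}

# cosine similarity of two numeric vectors; NA-free inputs assumed
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

as_ymd <- function(x) {
  d <- as.Date(x)
  if (anyNA(d)) stop("unparseable date value: ", paste(x[is.na(d)], collapse = ", "))
  d
}

# stable stopifnot-with-message
abort_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

# deterministic row order helper: order by columns given as character vector
order_by <- function(df, cols) {
  if (nrow(df) == 0) return(df)
  df[do.call(order, unname(as.list(df[cols]))), , drop = FALSE]
}

reset_rownames <- function(df) { rownames(df) <- NULL; df }
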
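#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. Nothing here is exported.

stop2 <- function(...) stop(..., call. = FALSE)

warn2 <- function(...) warning(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_prop <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

is_pos <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
}

#' Deterministic TSV writer
#'
#' All pipeline outputs go through this writer so that repeated runs with the
#' same seed produce byte-identical files: fixed quoting, "." decimal mark,
#' 15 significant digits, "\n" line endings.
#' @noRd
write_tsv_det <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) {
    out[[j]] <- formatC(df[[j]], digits = 15, format = "g")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out)) {
    lines <- do.call(paste, c(unname(as.list(out)), list(sep = "\t")))
    writeLines(lines, con)
  }
  invisible(path)
}

read_tsv_simple <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# FNV-1a 32-bit hash of a character string, returned as 8 hex digits.
# Used for the run-manifest config hash; avoids a digest dependency and is
# deterministic across platforms.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte touches only the low 8 bits; keeps h a double < 2^32
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by 16777619 without overflow: split into halves
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Jaccard index of two sets
#'
#' Defined as |A ∩ B| / |A ∪ B|. Two empty sets are treated as identical
#' (Jaccard 1), which keeps the comparison report well-defined for empty
#' method runs.
#'
#' @param a,b character vectors (treated as sets).
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' jaccard(c("a", "b"), c("b", "c"))
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}
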
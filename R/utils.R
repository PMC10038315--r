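# Internal helpers shared across modules.

# Classed conditions so callers (and the CLI) can distinguish domain errors
# (inconsistent posets, contradictory trees) from usage/parse errors.
phgt_stop <- function(message, class, ...) {
  extra <- list(...)
  cond <- structure(
    class = c(class, "posethgt_error", "error", "condition"),
    c(list(message = message, call = sys.call(-1)), extra)
  )
  stop(cond)
}

phgt_note <- function(...) {
  message("posetHGT: ", ...)
}

# Pairs are carried as a 2-column character matrix (lesser, greater).
as_pair_matrix <- function(pairs) {
  if (is.null(pairs) || (is.list(pairs) && length(pairs) == 0L)) {
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("lesser", "greater"))))
  }
  if (is.matrix(pairs)) {
    stopifnot(ncol(pairs) == 2L)
    m <- pairs
    storage.mode(m) <- "character"
  } else if (is.data.frame(pairs)) {
    m <- cbind(as.character(pairs[[1L]]), as.character(pairs[[2L]]))
  } else if (is.list(pairs)) {
    stopifnot(all(lengths(pairs) == 2L))
    m <- do.call(rbind, lapply(pairs, as.character))
  } else {
    stop("pairs must be a 2-column matrix, data.frame, or list of pairs")
  }
  dimnames(m) <- list(NULL, c("lesser", "greater"))
  m <- m[!duplicated(pair_keys(m)), , drop = FALSE]
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

pair_keys <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  paste(m[, 1L], m[, 2L], sep = "\r")
}

has_pair <- function(m, a, b) {
  any(m[, 1L] == a & m[, 2L] == b)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
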
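## Small shared helpers.

#' Round half away from zero
#'
#' Percentages in catalog summaries are printed as integers; base `round()`
#' uses banker's rounding, which would turn 37.5 into 38 but 86.5 into 86.
#' Summaries therefore round half away from zero and always retain the raw
#' value alongside.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## FOG/HOG identifiers: prefix + zero-padded integer, >= 5 digits, widening
## when the count overflows.
formatGroupId <- function(prefix, i) {
  width <- pmax(5L, nchar(as.character(i)))
  sprintf("%s%0*d", prefix, width, i)
}

groupIdNumber <- function(ids) {
  suppressWarnings(as.integer(sub("^[A-Za-z]+", "", ids)))
}

## Next n unused FOG (or HOG) ids given the ids already in use.
nextGroupIds <- function(existing, n, prefix = "FOG") {
  nums <- groupIdNumber(existing)
  top <- if (length(nums) && any(!is.na(nums))) max(nums, na.rm = TRUE) else 0L
  formatGroupId(prefix, top + seq_len(n))
}

## Union-find with path halving; `n` elements, returns an environment of ops.
unionFind <- function(n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[rb] <<- ra
    invisible(NULL)
  }
  list(find = find, union = union,
       components = function() vapply(seq_len(n), find, integer(1)))
}

## Open a text connection, transparently gunzipping *.gz paths.
openInput <- function(path) {
  if (is.character(path) && length(path) == 1L && grepl("\\.gz$", path)) {
    gzfile(path, "rt")
  } else if (is.character(path)) {
    file(path, "rt")
  } else {
    path
  }
}

readInputLines <- function(path) {
  con <- openInput(path)
  on.exit(close(con), add = TRUE)
  readLines(con, warn = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
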
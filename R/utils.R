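## Internal helpers shared across modules.

abort_if <- function(cond, ..., class = "spikecast_error") {
  if (isTRUE(cond)) {
    stop(structure(
      class = c(class, "error", "condition"),
      list(message = paste0(...), call = sys.call(-1))
    ))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Apply f elementwise over two parallel parameter trees (nested lists of
## numeric arrays), preserving structure.
map2_params <- function(a, b, f) {
  if (is.list(a)) {
    abort_if(!is.list(b) || length(a) != length(b),
             "parameter trees have mismatched structure")
    out <- mapply(map2_params, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    names(out) <- names(a)
    return(out)
  }
  abort_if(length(a) != length(b),
           "parameter shape mismatch: ", length(a), " vs ", length(b))
  r <- f(a, b)
  attributes(r) <- attributes(a)
  r
}

map_params <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, map_params, f = f)
    names(out) <- names(a)
    return(out)
  }
  r <- f(a)
  attributes(r) <- attributes(a)
  r
}

## Flatten a parameter tree to a single numeric vector (for norms/diagnostics).
flatten_params <- function(a) {
  if (is.list(a)) return(unlist(lapply(a, flatten_params), use.names = FALSE))
  as.numeric(a)
}

zeros_like <- function(a) map_params(a, function(x) x * 0)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

as_date_strict <- function(x, what = "date") {
  d <- tryCatch(as.Date(x), error = function(e) NA)
  abort_if(anyNA(d), "unparsable ", what, ": ", paste(x[is.na(d)], collapse = ", "))
  d
}

sigmoid <- function(x) 1 / (1 + exp(-x))
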
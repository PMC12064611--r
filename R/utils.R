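# shared input checks; all user-facing errors go through rlang::abort with a
# class so callers (and the CLI) can branch on error kinds

stop_fbbc <- function(msg, class, ...) {
  abort(msg, class = c(class, "fbbc_error"), ...)
}

check_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_fbbc(sprintf("`%s` must be a single number.", name), "fbbc_argument_error")
  }
  ok <- if (strict) x > min else x >= min
  if (!ok) {
    cmp <- if (strict) ">" else ">="
    stop_fbbc(sprintf("`%s` must be %s %g (got %g).", name, cmp, min, x),
              "fbbc_argument_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_scalar_number(x, name, min = min)
  if (x != as.integer(x)) {
    stop_fbbc(sprintf("`%s` must be a whole number (got %g).", name, x),
              "fbbc_argument_error")
  }
  as.integer(x)
}

# restore class/attributes after dplyr verbs strip a subclass
restore_attrs <- function(new, old, extra = character()) {
  keep <- c("fps", "video_name", "frame_size", "scheme", "provenance",
            "params", "clusters", extra)
  for (a in keep) {
    if (!is.null(attr(old, a))) attr(new, a) <- attr(old, a)
  }
  class(new) <- class(old)
  new
}
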
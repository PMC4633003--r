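# internal validation helpers

stop_fvri <- function(msg, ..., class = "fvri_error") {
  rlang::abort(paste0(msg, ...), class = class)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_fvri(sprintf("`%s` must be a single finite number.", name))
  }
  low_ok <- if (strict_lower) x > lower else x >= lower
  high_ok <- if (strict_upper) x < upper else x <= upper
  if (!low_ok || !high_ok) {
    stop_fvri(sprintf(
      "`%s` = %g is outside the admissible range %s%g, %g%s.",
      name, x, if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ))
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_fvri(sprintf(
      "%s is missing required column(s): %s.",
      what, paste(missing, collapse = ", ")
    ), class = "fvri_schema_error")
  }
  invisible(df)
}

# deterministic child seeds below 2^31, derived from one master seed
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# minimal pipe-free markdown table for reports
md_table <- function(df, digits = 3) {
  fmt <- function(x) {
    if (is.numeric(x)) formatC(x, digits = digits, format = "g") else as.character(x)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = 1L)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, rule, body)
}
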
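# Internal helpers shared across modules.

hgf_stop <- function(message, class = character(), call. = FALSE, ...) {
  cond <- errorCondition(message, ..., class = c(class, "hgf_error"))
  stop(cond)
}

hgf_warn <- function(message, class = character()) {
  warning(warningCondition(message, class = c(class, "hgf_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Euclidean norm with the package-wide numerical floor: vectors below
# 1e-12 are treated as zero (degenerate) vectors.
vec_norm <- function(x) sqrt(sum(x^2))

HGF_NORM_FLOOR <- 1e-12

# Resolve a text source to its lines.  A single newline-free string is a
# file path (missing files are an error); anything else is taken as the
# content itself (connection or character vector of lines).
source_lines <- function(source) {
  if (inherits(source, "connection")) {
    return(readLines(source, encoding = "UTF-8", warn = FALSE))
  }
  source <- as.character(source)
  if (length(source) == 1L && !grepl("\n", source, fixed = TRUE)) {
    if (!file.exists(source)) {
      hgf_stop(sprintf("file not found: %s", source), "hgf_invalid_input")
    }
    return(readLines(source, encoding = "UTF-8", warn = FALSE))
  }
  # split embedded newlines while preserving blank lines (record separators)
  strsplit(paste(source, collapse = "\n"), "\n", fixed = TRUE)[[1L]]
}
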
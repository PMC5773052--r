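#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map2 map_chr map_int map_dbl map_lgl pmap keep imap
#' @importFrom tidyr unnest nest
NULL

# Character offsets are 0-based, half-open throughout: a mention [start, end)
# over the raw document text. R's substr is 1-based and inclusive.
slice_text <- function(text, start, end) {
  substr(rep_len(text, length(start)), start + 1L, end)
}

# Run code with a temporary RNG state derived from `seed`, restoring the
# caller's state afterwards, so generators are deterministic without
# clobbering the session RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

is_go_id <- function(x) grepl("^GO:[0-9]{7}$", x)

is_taxid <- function(x) grepl("^[1-9][0-9]*$", x)

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "locrex")
  if (!nzchar(path)) {
    abort(paste0("built-in data file not found: ", file))
  }
  path
}

read_tsv_table <- function(path, col_names) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  missing <- setdiff(col_names, names(df))
  if (length(missing) > 0) {
    abort(paste0("table ", path, " lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  as_tibble(df)
}
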
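## Internal helpers shared across modules.

#' Well identifiers for a 96-well plate
#'
#' Builds canonical `"A01"`-style identifiers (rows A-H, columns 1-12).
#'
#' @param rows Row letters (subset of `LETTERS[1:8]`).
#' @param cols Column numbers (subset of `1:12`).
#' @return Character vector of well ids, row-major.
#' @examples
#' well_ids("A", 1:3)
#' @export
well_ids <- function(rows = LETTERS[1:8], cols = 1:12) {
  stopifnot(all(rows %in% LETTERS[1:8]), all(cols %in% 1:12))
  as.vector(t(outer(rows, cols, function(r, c) sprintf("%s%02d", r, c))))
}

is_valid_well_id <- function(x) {
  grepl("^[A-H](0[1-9]|1[0-2])$", x)
}

## Deterministic 31-bit child seed from a master seed and a string key, so each
## chemical/assay gets its own stream and adding one never perturbs the others.
child_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(as.character(key))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

with_child_seed <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(child_seed(seed, key))
  force(expr)
}

## stop() with a consistent message prefix for validation failures
validation_error <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "zebratox_validation_error")
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    validation_error("%s is missing required column(s): %s",
                     what, paste(missing, collapse = ", "))
  }
  invisible(df)
}
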
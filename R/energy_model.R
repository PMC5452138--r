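# Nearest-neighbour energy model: plain-text parameter file reader.
#
# The shipped parameter set (inst/extdata/nn_params.txt) is a simplified
# Turner-style table: stacking free energies for the six allowed pair steps,
# tabulated hairpin/bulge/internal loop penalties (sizes up to 30 nt,
# logarithmic extrapolation beyond), and affine multibranch-loop terms.
# Dangling ends, terminal mismatches and helix-end penalties are deliberately
# omitted; see the methods vignette.

PAIR_NAMES <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Read a nearest-neighbour energy parameter file
#'
#' The file is whitespace-delimited with named sections: `[stack]` (lines
#' `outer inner dG` over the six allowed pairs), `[hairpin]`, `[bulge]`,
#' `[internal]` (lines `size dG`), `[multiloop]` (`a`, `b`, `c` affine terms)
#' and `[options]` (`min_loop`, `max_internal`, `loop_coef`). Lines starting
#' with `#` are comments.
#'
#' @param path parameter file; defaults to the shipped set.
#' @return object of class `energy_model`: list with `stack` (6x6 matrix,
#'   dimnames the pair names), `hairpin`/`bulge`/`internal` (penalty by loop
#'   size, `Inf` where forbidden), `ml_a`, `ml_b`, `ml_c`, `min_loop`,
#'   `max_internal`, `loop_coef`.
#' @export
read_energy_model <- function(path = system.file("extdata", "nn_params.txt",
                                                 package = "itsfold")) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- NA_character_
  stack <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_NAMES, PAIR_NAMES))
  tabs <- list(hairpin = numeric(0), bulge = numeric(0), internal = numeric(0))
  ml <- c(a = NA_real_, b = NA_real_, c = NA_real_)
  opts <- c(min_loop = NA_real_, max_internal = NA_real_, loop_coef = NA_real_)
  for (l in lines) {
    if (grepl("^\\[.*\\]$", l)) { section <- gsub("[][]", "", l); next }
    f <- strsplit(l, "\\s+")[[1]]
    if (section == "stack") {
      if (!(f[1] %in% PAIR_NAMES && f[2] %in% PAIR_NAMES))
        stop("unknown pair in stack table: ", l)
      stack[f[1], f[2]] <- as.numeric(f[3])
    } else if (section %in% names(tabs)) {
      tabs[[section]][as.integer(f[1])] <- as.numeric(f[2])
    } else if (section == "multiloop") {
      ml[f[1]] <- as.numeric(f[2])
    } else if (section == "options") {
      opts[f[1]] <- as.numeric(f[2])
    } else stop("line outside a known section: ", l)
  }
  if (anyNA(stack)) stop("incomplete stack table")
  if (anyNA(ml) || anyNA(opts)) stop("incomplete multiloop/options section")
  fix <- function(v) { v[is.na(v)] <- Inf; v }
  model <- list(stack = stack,
                hairpin = fix(tabs$hairpin), bulge = fix(tabs$bulge),
                internal = fix(tabs$internal),
                ml_a = unname(ml["a"]), ml_b = unname(ml["b"]), ml_c = unname(ml["c"]),
                min_loop = as.integer(opts["min_loop"]),
                max_internal = as.integer(opts["max_internal"]),
                loop_coef = unname(opts["loop_coef"]))
  if (any(model$hairpin[seq_len(min(model$min_loop - 1, length(model$hairpin)))] < Inf))
    stop("hairpin table allows loops below min_loop")
  class(model) <- "energy_model"
  model
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf(paste0("<energy_model> %d pair steps; loop tables to size %d",
                     " (log extrapolation, coef %.2f); multiloop a=%.2f b=%.2f c=%.2f;",
                     " min hairpin loop %d\n"),
              sum(is.finite(x$stack)), length(x$hairpin), x$loop_coef,
              x$ml_a, x$ml_b, x$ml_c, x$min_loop))
  invisible(x)
}

.model_cache <- new.env(parent = emptyenv())

#' Default shipped energy model
#'
#' @return the cached [read_energy_model()] result for the shipped parameters.
#' @export
default_energy_model <- function() {
  if (is.null(.model_cache$model))
    .model_cache$model <- read_energy_model()
  .model_cache$model
}

# penalty lookup with logarithmic extrapolation beyond the table end
loop_penalty <- function(table, size, coef) {
  if (size <= 0) return(Inf)
  last <- length(table)
  if (size <= last) return(table[size])
  table[last] + coef * log(size / last)
}
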
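# Internal helpers shared across modules.

# Run code with a temporary RNG state so that seeded simulators never disturb
# the caller's random stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

.is_dna <- function(x) {
  is.character(x) & !is.na(x) & nzchar(x) & grepl("^[ACGT]+$", x)
}

.check_dna <- function(x, arg = "sequence") {
  bad <- !.is_dna(x)
  if (any(bad)) {
    abort(
      paste0("`", arg, "` must contain only A/C/G/T characters."),
      class = "motifsyntax_dna_error"
    )
  }
  invisible(x)
}

# Reverse complement of a character vector of DNA strings.
.rc_string <- function(x) {
  .check_dna(x)
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Reverse complement of a 4 x L matrix with rows in A,C,G,T order:
# swap A<->T and C<->G, then reverse the columns.
.rc_matrix <- function(m) {
  out <- m[4:1, rev(seq_len(ncol(m))), drop = FALSE]
  rownames(out) <- .BASES
  out
}

.check_matrix4 <- function(m, arg = "matrix") {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != 4L) {
    abort(paste0("`", arg, "` must be a numeric 4 x L matrix (rows A,C,G,T)."),
          class = "motifsyntax_parameter_error")
  }
  if (!all(is.finite(m))) {
    abort(paste0("`", arg, "` contains non-finite entries."),
          class = "motifsyntax_parameter_error")
  }
  invisible(m)
}

.param_error <- function(msg) abort(msg, class = "motifsyntax_parameter_error")
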
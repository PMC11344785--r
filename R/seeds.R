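#' Derive a reproducible task seed from a master seed and labels
#'
#' Per-task seeds are derived by hashing the master seed together with a
#' string label (task name, taxon, variable, source), so that results do not
#' depend on the order in which taxa or studies are processed. The hash is a
#' polynomial rolling hash over the UTF-8 bytes of the label, reduced modulo
#' the Mersenne prime 2^31 - 1 so the result is always a valid R integer
#' seed.
#'
#' @param master integer master seed.
#' @param ... character or numeric labels identifying the task; coerced to
#'   character and concatenated with `""` separators.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "reconstruct", "Rhabdosphaera clavigera HET", "volume_um3")
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  label <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                        character(1L)), collapse = "")
  mod <- 2147483647
  h <- as.numeric(master) %% mod
  for (b in utf8ToInt(label)) {
    # 31-ary rolling hash; doubles stay exact (< 2^53) between reductions
    h <- (h * 31 + b) %% mod
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards. Used by every stochastic operation so that the
# global RNG stream is never consumed implicitly.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
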
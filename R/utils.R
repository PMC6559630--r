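#' Derive a child RNG seed from a master seed
#'
#' A stated deterministic scheme (master plus a large prime times the
#' index, folded into the 32-bit signed range) so that every randomized
#' stage of a run draws from its own reproducible stream and serial and
#' parallel executions agree.
#'
#' @param master integer master seed.
#' @param index nonnegative integer stream index.
#' @return a single integer seed in [1, 2^31 - 2].
#' @export
childSeed <- function(master, index) {
  as.integer((as.numeric(master) + 104729 * as.numeric(index)) %%
               2147483646) + 1L
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
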
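# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a parent seed and a stream index (kept < 2^31)
#' @noRd
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 69069 + 12345 * as.numeric(index)) %% 2147483647)
}

# Structured error helper: class is prefixed so callers can distinguish
# configuration, input and numerical failures.
bimr_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("bimr_", class), "bimr_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Drop-log bookkeeping -----------------------------------------------------
# Every filtering operation attaches a data.frame of (snp_id, reason, detail)
# to its result so pipeline runs can write a complete per-SNP audit trail.

empty_drop_log <- function() {
  data.frame(snp_id = character(), reason = character(), detail = character(),
             stringsAsFactors = FALSE)
}

add_drops <- function(x, snp_id, reason, detail = "") {
  log <- attr(x, "drops")
  if (is.null(log)) log <- empty_drop_log()
  if (length(snp_id)) {
    log <- rbind(log, data.frame(snp_id = as.character(snp_id),
                                 reason = reason,
                                 detail = rep_len(as.character(detail), length(snp_id)),
                                 stringsAsFactors = FALSE))
  }
  attr(x, "drops") <- log
  x
}

#' Retrieve the per-SNP drop log of a table produced by a filtering operation
#'
#' @param x an object returned by a \pkg{bimr} filtering or harmonization
#'   operation.
#' @return a data.frame with columns \code{snp_id}, \code{reason},
#'   \code{detail} (possibly zero rows).
#' @export
drop_log <- function(x) {
  log <- attr(x, "drops")
  if (is.null(log)) empty_drop_log() else log
}

# Carry attributes through data.frame subsetting
keep_gwas_attrs <- function(new, old) {
  for (a in c("trait_name", "is_binary", "n_cases", "n_controls", "class")) {
    attr(new, a) <- attr(old, a)
  }
  new
}
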
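# 32-bit FNV-1a hash of a serialized R object; cheap content fingerprint for
# run manifests (no cryptographic claims)
#' Content hash of an R object
#'
#' Stable fingerprint used in run manifests and series metadata so a run can
#' be tied to the exact model and configuration that produced it.
#'
#' @param x any serialisable object.
#' @return an 8-character hex string.
#' @export
object_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  if (length(raw) > 65536) {
    idx <- unique(as.integer(seq(1, length(raw), length.out = 65536)))
    raw <- c(raw[idx], serialize(length(raw), NULL, version = 2))
  }
  h <- 2166136261
  for (b in as.integer(raw)) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)   # xor touches only the low byte
    h <- (h * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}
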
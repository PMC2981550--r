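# Internal constants and small helpers shared across modules.

# Canonical residue ordering used by every one-hot encoding.  A column
# permutation cannot affect any downstream statistic or classifier, so the
# standard alphabetical order of the 20 one-letter codes is fixed once here.
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Annotation namespaces the pipeline knows about.
NAMESPACES <- c("kegg", "go_bp", "go_cc", "go_mf", "pfam", "interpro", "string_ppi")

#' Canonical amino-acid alphabet
#'
#' The fixed residue ordering (alphabetical one-letter codes) used for all
#' one-hot encodings.  `"X"` denotes an unknown residue or window padding and
#' always encodes as an all-zero block.
#'
#' @return Character vector of the 20 standard one-letter amino-acid codes.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() AA_STANDARD

# Deterministic child seed for a named sub-stream.  Keeps seeds within the
# 32-bit integer range R requires.
child_seed <- function(seed, offset) {
  (abs(as.integer(seed)) + as.integer(offset)) %% 2147483629L
}

# Consistent assertion helper: abort with a uniform message style.
check_that <- function(ok, msg, class = "hetphos_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}

# Collapse a few offending values into a readable message fragment.
some_of <- function(x, n = 5) {
  x <- as.character(x)
  if (length(x) > n) {
    paste0(paste(x[seq_len(n)], collapse = ", "), ", ... (", length(x), " total)")
  } else {
    paste(x, collapse = ", ")
  }
}
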
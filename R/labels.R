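#' Attribution label vocabulary
#'
#' The closed set of five attribution labels a treatment mention can carry:
#' `pt` (actual use by the patient of interest), `pt-gen` (tied to the patient
#' but no actual use indicated), `cg` (tied to the caregiver), `others` (tied
#' to other specific individuals), and `gen` (not tied to anyone specific).
#'
#' @return Character vector of the five labels, in canonical order.
#' @export
#' @examples
#' attribution_labels()
attribution_labels <- function() {
  c("pt", "pt-gen", "cg", "others", "gen")
}

#' Typed-BIO tag alphabet
#'
#' The 11-symbol tag alphabet used by the joint mention/attribution tagger:
#' `O` plus `B-c` and `I-c` for each attribution label `c`. `O` is always the
#' first symbol; deterministic tie-breaking in decoding prefers lower indices.
#'
#' @return Character vector of length 11.
#' @export
crf_labels <- function() {
  labs <- attribution_labels()
  c("O", as.vector(rbind(paste0("B-", labs), paste0("I-", labs))))
}

# split a tag into its prefix ("O"/"B"/"I") and attribution class (NA for O)
parse_tag <- function(tags) {
  pre <- ifelse(tags == "O", "O", substr(tags, 1L, 1L))
  cls <- ifelse(tags == "O", NA_character_, substr(tags, 3L, nchar(tags)))
  list(prefix = pre, class = cls)
}

assert_valid_labels <- function(labels) {
  bad <- setdiff(labels, attribution_labels())
  if (length(bad) > 0L) {
    stop("unknown attribution label(s): ", paste(unique(bad), collapse = ", "))
  }
  invisible(TRUE)
}

#' Check that a tag sequence is valid typed BIO
#'
#' A sequence is valid when every tag belongs to the 11-symbol alphabet and
#' every `I-c` is preceded by `B-c` or `I-c` of the same class `c`.
#'
#' @param tags Character vector of tags.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_bio <- function(tags) {
  if (length(tags) == 0L) return(TRUE)
  if (!all(tags %in% crf_labels())) return(FALSE)
  p <- parse_tag(tags)
  for (t in seq_along(tags)) {
    if (p$prefix[t] == "I") {
      if (t == 1L) return(FALSE)
      if (p$prefix[t - 1L] == "O") return(FALSE)
      if (!identical(p$class[t - 1L], p$class[t])) return(FALSE)
    }
  }
  TRUE
}

#' Merge the five attribution labels into the binary pt / non-pt regime
#'
#' For catalogue building only the `pt` class matters; the remaining four
#' labels (`pt-gen`, `cg`, `others`, `gen`) are pooled into `non-pt`.
#'
#' @param label Character vector of attribution labels.
#' @return Character vector over `{"pt", "non-pt"}`.
#' @export
#' @examples
#' binary_merge(c("pt", "pt-gen", "cg", "gen"))
binary_merge <- function(label) {
  assert_valid_labels(label)
  ifelse(label == "pt", "pt", "non-pt")
}
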
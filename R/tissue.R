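#' Tissue classes of the diseased vessel wall
#'
#' The five material regions carried by a labeled vessel mesh: healthy wall
#' (artery), mixed, fibrous, lipid, and calcified tissue. The integer codes
#' are the on-disk encoding of the `"tissue"` cell-data field in VTU/MSH
#' files.
#'
#' @return named integer vector mapping class name to integer code.
#' @examples
#' tissue_classes()
#' @export
tissue_classes <- function() {
  c(artery = 1L, mixed = 2L, fibrous = 3L, lipid = 4L, calcium = 5L)
}

#' @rdname tissue_classes
#' @param label character vector of class names or integer vector of codes.
#' @return `as_tissue()` returns a factor over the five classes.
#' @export
as_tissue <- function(label) {
  tc <- tissue_classes()
  if (is.numeric(label)) {
    bad <- !(label %in% tc)
    if (any(bad)) stop("unknown tissue code(s): ", paste(unique(label[bad]), collapse = ", "))
    label <- names(tc)[match(label, tc)]
  }
  label <- as.character(label)
  bad <- !(label %in% names(tc))
  if (any(bad)) stop("unknown tissue label(s): ", paste(unique(label[bad]), collapse = ", "))
  factor(label, levels = names(tc))
}
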
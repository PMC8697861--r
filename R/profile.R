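#' Base-editor profile
#'
#' Describes the editor geometry guide design and quantification share: the
#' PAM, the protospacer length, and the deaminase editing window expressed as
#' distances upstream of the PAM.  The defaults describe Target-AID used with
#' SpCas9: a 20-nt protospacer, an NGG PAM, and efficient C-to-T conversion
#' 16-19 bp upstream of the PAM (protospacer positions 2-5 counted from the
#' 5' end).  The conversion chemistry is fixed (C-to-T on the guide strand).
#'
#' Distance-to-PAM convention: the protospacer base immediately adjacent to
#' the PAM is 1 bp upstream of it, so position p (5'->3') lies
#' `protospacer_length - p + 1` bp upstream.
#'
#' @param pam_pattern IUPAC PAM pattern, default `"NGG"`.
#' @param protospacer_length protospacer length in nt, default 20.
#' @param window_from,window_to editing-window bounds in bp upstream of the
#'   PAM, defaults 16 and 19.
#' @return an object of class `editor_profile`.
#' @export
editor_profile <- function(pam_pattern = "NGG", protospacer_length = 20L,
                           window_from = 16L, window_to = 19L) {
  if (!is_iupac(pam_pattern) || nchar(pam_pattern) < 1) {
    abort("pam_pattern must be a non-empty IUPAC string")
  }
  if (!(window_from >= 1 && window_from <= window_to &&
        window_to <= protospacer_length)) {
    abort("require 1 <= window_from <= window_to <= protospacer_length")
  }
  structure(list(
    pam_pattern = pam_pattern,
    protospacer_length = as.integer(protospacer_length),
    window_from = as.integer(window_from),
    window_to = as.integer(window_to),
    conversion = c(from = "C", to = "T")
  ), class = "editor_profile")
}

#' @export
print.editor_profile <- function(x, ...) {
  b <- window_bounds(x)
  cat("<editor_profile> ", x$protospacer_length, "-nt protospacer + ",
      x$pam_pattern, " PAM; C->T window ", x$window_from, "-", x$window_to,
      " bp upstream of PAM (protospacer positions ", b[1], "-", b[2], ")\n",
      sep = "")
  invisible(x)
}

# Protospacer positions (5'->3') covered by the editing window.
window_bounds <- function(profile) {
  c(profile$protospacer_length - profile$window_to + 1L,
    profile$protospacer_length - profile$window_from + 1L)
}
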
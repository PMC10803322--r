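#' Canonical 21-marker analysis set
#'
#' The analysis operates on 21 reflective markers placed on anatomical
#' landmarks: head (HE), 7th cervical vertebra (C7), 10th thoracic vertebra
#' (T10), acromions (LAC/RAC), lateral elbows (LLELB/RLELB), lateral wrists
#' (LWRB/RWRB), iliac crests (LIC/RIC), greater trochanters (LGT/RGT),
#' lateral knees (LLK/RLK), lateral ankles (LLA/RLA), heels (LHEEL/RHEEL)
#' and 5th metatarsals (LFT5/RFT5). The order returned here is the fixed
#' canonical order used for every kinectome row/column index in the
#' package, so matrices from different subjects and conditions are always
#' directly comparable.
#'
#' @return Character vector of the 21 canonical marker labels, in order.
#' @export
kinectome_markers <- function() {
  c("HE", "C7", "T10", "LAC", "RAC",
    "LLELB", "RLELB", "LWRB", "RWRB",
    "LIC", "RIC", "LGT", "RGT",
    "LLK", "RLK", "LLA", "RLA",
    "LHEEL", "RHEEL", "LFT5", "RFT5")
}

# markers belonging to the trunk group (coupled on the ML axis in the
# synthetic model) and the limb group (coupled on AP)
trunk_group <- function() c("HE", "C7", "T10", "LAC", "RAC")
limb_group  <- function() c("LLELB", "RLELB", "LWRB", "RWRB", "LLK", "RLK")

#' Marker-set definition with vendor aliases
#'
#' Describes how vendor-specific marker labels map onto the 21 canonical
#' labels. Datasets exported from acquisition software frequently use
#' house conventions (e.g. `HEAD` for `HE`); an alias table resolves them.
#'
#' @param aliases Named character vector mapping vendor labels (names) to
#'   canonical labels (values), or `NULL` for no aliases.
#' @return An object of class `marker_set_definition` with elements
#'   `canonical_labels` and `aliases`.
#' @examples
#' def <- marker_set_definition(c(HEAD = "HE", CERV7 = "C7"))
#' @export
marker_set_definition <- function(aliases = NULL) {
  canon <- kinectome_markers()
  if (!is.null(aliases)) {
    if (is.null(names(aliases)) || any(names(aliases) == ""))
      stop("aliases must be a named character vector (vendor -> canonical)")
    bad <- setdiff(unname(aliases), canon)
    if (length(bad))
      stop("alias targets are not canonical labels: ", paste(bad, collapse = ", "))
  }
  structure(list(canonical_labels = canon, aliases = aliases),
            class = "marker_set_definition")
}

#' Read a marker alias table
#'
#' Reads a two-column delimited table (vendor label, canonical label) into
#' a [marker_set_definition()].
#'
#' @param path Path to a delimited file with columns `vendor` and
#'   `canonical` (header required).
#' @return A `marker_set_definition`.
#' @export
read_marker_aliases <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("vendor", "canonical") %in% names(tab)))
    stop("alias table must have columns 'vendor' and 'canonical'")
  al <- stats::setNames(tab$canonical, tab$vendor)
  marker_set_definition(al)
}

# static body-schematic layout used only for network figures; x is
# mediolateral (left negative), y is caudo-cranial, arbitrary units
body_layout <- function() {
  data.frame(
    marker = kinectome_markers(),
    x = c(0, 0, 0, -0.16, 0.16,
          -0.27, 0.27, -0.32, 0.32,
          -0.12, 0.12, -0.17, 0.17,
          -0.14, 0.14, -0.14, 0.14,
          -0.17, 0.17, -0.12, 0.12),
    y = c(1.00, 0.90, 0.74, 0.88, 0.88,
          0.68, 0.68, 0.52, 0.52,
          0.56, 0.56, 0.50, 0.50,
          0.28, 0.28, 0.06, 0.06,
          0.02, 0.02, 0.00, 0.00),
    stringsAsFactors = FALSE
  )
}
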
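#' Canonical amino-acid column order
#'
#' The 20 standard amino acids in the native column order of PSI-BLAST
#' ASCII PSSM output (`-out_ascii_pssm`). Every matrix, descriptor and
#' feature name in the package indexes amino acids in this order.
#'
#' @format Character vector of 20 single-letter codes.
#' @export
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y")

#' Default 10-group reduced amino-acid alphabet
#'
#' Partition of the 20 amino acids into 10 physicochemical groups
#' (aromatic FYW; the hydrophobic pairs ML and IV; small ATS; amide/basic
#' NH; acidic/amide QED; basic RK; and singletons C, G, P). Ten letters is
#' about the smallest alphabet that still supports reasonable fold
#' modelling, which motivates the reduced-profile descriptor.
#'
#' @seealso [reduction_scheme()], [reduce_pssm()], [rpssm()]
#' @format Named list of 10 character vectors partitioning [AA_ORDER].
#' @export
DEFAULT_REDUCTION <- list(
  FYW = c("F", "Y", "W"),
  ML  = c("M", "L"),
  IV  = c("I", "V"),
  ATS = c("A", "T", "S"),
  NH  = c("N", "H"),
  QED = c("Q", "E", "D"),
  RK  = c("R", "K"),
  C   = "C",
  G   = "G",
  P   = "P"
)

#' Build and validate a reduced-alphabet scheme
#'
#' @param groups Named list of character vectors that must form a disjoint
#'   cover of the 20 standard amino acids, with exactly 10 groups.
#' @return An object of class `reduction_scheme`: the validated group
#'   list, with group names used in RPSSM feature names.
#' @examples
#' sch <- reduction_scheme()
#' length(sch$groups)
#' @export
reduction_scheme <- function(groups = DEFAULT_REDUCTION) {
  if (!is.list(groups) || length(groups) != 10L) {
    stop_validation("a reduction scheme must have exactly 10 groups")
  }
  letters_all <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(letters_all)) {
    stop_validation("reduction groups overlap: ",
                    paste(letters_all[duplicated(letters_all)], collapse = ", "))
  }
  if (!setequal(letters_all, AA_ORDER)) {
    stop_validation("reduction groups must cover the 20 standard amino acids")
  }
  nm <- names(groups)
  if (is.null(nm) || any(!nzchar(nm))) {
    nm <- vapply(groups, paste0, "", collapse = "")
  }
  structure(list(groups = groups, group_names = nm),
            class = "reduction_scheme")
}
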
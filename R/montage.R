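# The 31-channel wet-electrode 10/20 montage used throughout: labels in
# acquisition order plus flat 2-D scalp coordinates (unit disc, x = right,
# y = anterior) for topography rendering and for the simulator's spatial
# projection model.

.montage_table <- function() {
  tab <- matrix(c(
    # label      x       y
    "Fp1",  -0.26,  0.78,
    "Fp2",   0.26,  0.78,
    "F7",   -0.67,  0.48,
    "F3",   -0.34,  0.42,
    "F4",    0.34,  0.42,
    "F8",    0.67,  0.48,
    "FC5",  -0.59,  0.22,
    "FC1",  -0.20,  0.21,
    "FC2",   0.20,  0.21,
    "FC6",   0.59,  0.22,
    "T7",   -0.82,  0.00,
    "C3",   -0.41,  0.00,
    "Cz",    0.00,  0.00,
    "C4",    0.41,  0.00,
    "T8",    0.82,  0.00,
    "TP9",  -0.87, -0.26,
    "CP5",  -0.59, -0.22,
    "CP1",  -0.20, -0.21,
    "CP2",   0.20, -0.21,
    "CP6",   0.59, -0.22,
    "TP10",  0.87, -0.26,
    "P7",   -0.67, -0.48,
    "P3",   -0.34, -0.42,
    "Pz",    0.00, -0.41,
    "P4",    0.34, -0.42,
    "P8",    0.67, -0.48,
    "PO9",  -0.55, -0.72,
    "O1",   -0.26, -0.78,
    "Oz",    0.00, -0.80,
    "O2",    0.26, -0.78,
    "PO10",  0.55, -0.72), ncol = 3, byrow = TRUE)
  data.frame(label = tab[, 1],
             x = as.numeric(tab[, 2]),
             y = as.numeric(tab[, 3]),
             stringsAsFactors = FALSE)
}

#' Standard 31-channel 10/20 montage
#'
#' Returns the 31 electrode labels (Fp1 ... PO10) in acquisition order with
#' canonical flattened 10/20 scalp positions on the unit disc (x positive
#' toward the right ear, y positive toward the nasion). C3/C4 sit over left
#' and right sensorimotor cortex; CP1/CP2 are the centro-parietal sites used
#' for the bipolar SSSEP derivation.
#'
#' @return a data.frame of class `montage` with columns `label`, `x`, `y`.
#' @export
#' @examples
#' m <- make_montage()
#' nrow(m)            # 31
#' subset(m, label %in% c("C3", "C4"))
make_montage <- function() {
  m <- .montage_table()
  class(m) <- c("montage", "data.frame")
  m
}

montage_position <- function(montage, label) {
  i <- match(label, montage$label)
  if (anyNA(i)) stop("unknown channel(s): ",
                     paste(label[is.na(i)], collapse = ", "))
  cbind(x = montage$x[i], y = montage$y[i])
}
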
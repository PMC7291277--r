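# Kyte-Doolittle hydropathy scale; X (ambiguous) contributes 0.
KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0
)

# Net charge per residue at physiological pH; histidine counted half.
CHARGE_SCALE <- c(K = 1, R = 1, D = -1, E = -1, H = 0.5)

# Largest attainable |FI|: FI ranges over [-(1.151 + 1), 2.785 - 1.151]
# given <H> in [0,1] and |<R>| in [0,1]; 2 * 1.968 = 3.936 bounds the map
# below into [0, 1].
FI_MAX_ABS <- 3.936

#' Per-residue intrinsic disorder score (charge-hydropathy windowed index)
#'
#' Computes a sliding-window charge/hydropathy fold index per residue:
#' `FI(i) = 2.785 * <H> - |<R>| - 1.151`, where `<H>` is the mean
#' Kyte-Doolittle hydropathy over the window rescaled to `[0, 1]` via
#' `(KD + 4.5) / 9`, and `<R>` is the mean net charge (K, R: +1; D, E: -1;
#' H: +0.5). Negative `FI` indicates disorder. The returned score maps `FI`
#' into `[0, 1]` as `0.5 - FI / (2 * 3.936)` (clipped), so a residue with
#' `FI < 0` scores above 0.5 and is counted disordered at the conventional
#' 0.5 cutoff. X residues contribute zero hydropathy and zero charge.
#'
#' The window is truncated symmetrically at the sequence ends: at residue
#' `i` the effective half-width is `min((window - 1) / 2, i - 1, L - i)`.
#'
#' This is the built-in default of a pluggable disorder interface;
#' precomputed per-residue scores from any external predictor can be
#' supplied instead via [read_disorder_profile()].
#'
#' @param protein A one-row protein table or a list with `id` and
#'   `sequence`.
#' @param window Odd positive integer window width (residues). Default 51,
#'   a typical long-window setting for separating globular from disordered
#'   tracts.
#' @return Numeric vector of per-residue scores in `[0, 1]`, of length equal
#'   to the sequence length.
#' @examples
#' p <- list(id = "k25", sequence = strrep("K", 25))
#' all(compute_disorder(p, window = 5) > 0.5)  # poly-K is disordered
#' @export
compute_disorder <- function(protein, window = 51L) {
  if (length(window) != 1 || is.na(window) || window < 1 ||
      window %% 2 == 0) {
    mhl_stop("window must be an odd positive integer", "mhl_param_error")
  }
  seq <- protein$sequence
  if (length(seq) != 1) {
    mhl_stop("compute_disorder expects a single protein", "mhl_param_error")
  }
  aa <- strsplit(seq, "")[[1]]
  L <- length(aa)
  h <- (unname(KD_SCALE[aa]) + 4.5) / 9
  h[is.na(h)] <- 0.5 # defensive; validated input never hits this
  r <- unname(CHARGE_SCALE[aa])
  r[is.na(r)] <- 0
  hw <- pmin((window - 1L) %/% 2L, seq_len(L) - 1L, L - seq_len(L))
  ch <- c(0, cumsum(h))
  cr <- c(0, cumsum(r))
  lo <- seq_len(L) - hw
  hi <- seq_len(L) + hw
  n <- hi - lo + 1
  mean_h <- (ch[hi + 1] - ch[lo]) / n
  mean_r <- (cr[hi + 1] - cr[lo]) / n
  fi <- 2.785 * mean_h - abs(mean_r) - 1.151
  pmin(pmax(0.5 - fi / (2 * FI_MAX_ABS), 0), 1)
}

# Disorder profiles for a whole protein table: named list id -> scores.
disorder_profiles <- function(proteins, window = 51L) {
  out <- lapply(seq_len(nrow(proteins)), function(i) {
    compute_disorder(proteins[i, ], window = window)
  })
  stats::setNames(out, proteins$id)
}
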
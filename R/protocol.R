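#' Acquisition protocol for a diffusion-relaxation series
#'
#' A protocol is an ordered table of (b-value, echo time) pairs; entry i
#' describes volume i of every 4D series it is paired with.  Units are fixed
#' package-wide: b in s.mm^-2, TE in ms.
#'
#' @param b numeric vector of b-values (s.mm^-2), all >= 0.
#' @param te numeric vector of echo times (ms), all > 0, same length as `b`.
#' @return An object of class `decide_protocol`: a data.frame with columns
#'   `b` and `te` and attribute `n`.
#' @export
decide_protocol <- function(b, te) {
  if (length(b) == 0L || length(te) == 0L)
    stop("protocol must contain at least one (b, te) entry")
  if (length(b) != length(te))
    stop("b and te must have equal length")
  if (any(!is.finite(b)) || any(!is.finite(te)))
    stop("b and te must be finite")
  if (any(b < 0)) stop("all b-values must be >= 0")
  if (any(te <= 0)) stop("all echo times must be > 0")
  out <- data.frame(b = as.numeric(b), te = as.numeric(te))
  class(out) <- c("decide_protocol", "data.frame")
  out
}

#' @export
print.decide_protocol <- function(x, ...) {
  cat(sprintf("<decide_protocol> %d entries; %d unique b, %d unique TE\n",
              nrow(x), length(unique(x$b)), length(unique(x$te))))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

# The three acquisition subsets of the default placental protocol:
# all TEs at b = 0, all b at TE = 96 ms, and b in {50, 200} across seven TEs.
default_protocol_sets <- function() {
  b_all <- c(0, 50, 100, 150, 200, 400, 600)
  te_all <- c(81, 90, 96, 120, 150, 180, 210, 240, 270, 300)
  te_mix <- c(81, 96, 120, 150, 180, 210, 240)
  rbind(
    data.frame(b = 0, te = te_all),
    data.frame(b = b_all, te = 96),
    expand.grid(b = c(50, 200), te = te_mix)[, c("b", "te")]
  )
}

#' Build an acquisition protocol
#'
#' Either from a named preset or an explicit two-column (b, te) specification.
#' The `"decide_default"` preset is the union of three subsets: ten echo times
#' at b = 0 (T2 sampling), seven b-values at TE = 96 ms (diffusion sampling),
#' and b in {50, 200} s.mm^-2 at seven echo times 81-240 ms (joint sampling).
#' The subsets overlap in three entries; with `dedup = TRUE` the 28 unique
#' pairs are returned, otherwise all 31 rows.  Additional repeated volumes in
#' a real series can be declared via `repeats`.
#'
#' @param spec `"decide_default"` or a data.frame/matrix with columns (b, te).
#' @param dedup logical; drop duplicated (b, te) pairs. Default `FALSE`
#'   (repeated volumes are genuine acquisitions and matter for registration).
#' @param repeats optional data.frame with columns (b, te) of extra entries
#'   appended after the preset, e.g. to reproduce a longer dynamic series.
#' @return A [decide_protocol] ordered b-major then TE.
#' @export
build_protocol <- function(spec = "decide_default", dedup = FALSE,
                           repeats = NULL) {
  if (is.character(spec)) {
    if (!identical(spec, "decide_default"))
      stop("unknown protocol preset: ", spec)
    tab <- default_protocol_sets()
  } else {
    tab <- as.data.frame(spec)
    if (ncol(tab) < 2L) stop("explicit protocol needs columns (b, te)")
    names(tab)[1:2] <- c("b", "te")
  }
  if (!is.null(repeats)) {
    rep_tab <- as.data.frame(repeats)
    names(rep_tab)[1:2] <- c("b", "te")
    tab <- rbind(tab[, c("b", "te")], rep_tab[, c("b", "te")])
  }
  tab <- tab[order(tab$b, tab$te), , drop = FALSE]
  if (dedup) tab <- tab[!duplicated(tab[, c("b", "te")]), , drop = FALSE]
  rownames(tab) <- NULL
  decide_protocol(tab$b, tab$te)
}

#' Read / write a protocol CSV
#'
#' The on-disk format is a CSV with header `index,b_s_per_mm2,te_ms`.
#'
#' @param path file path.
#' @return `read_protocol` returns a [decide_protocol].
#' @export
read_protocol <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("b_s_per_mm2", "te_ms")
  if (!all(need %in% names(tab)))
    stop("malformed protocol CSV: expected columns ", paste(need, collapse = ", "))
  decide_protocol(tab$b_s_per_mm2, tab$te_ms)
}

#' @rdname read_protocol
#' @param protocol a [decide_protocol].
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "decide_protocol"))
  utils::write.csv(
    data.frame(index = seq_len(nrow(protocol)) - 1L,
               b_s_per_mm2 = protocol$b, te_ms = protocol$te),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
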
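# Short protein-change (HGVS-p "short") grammar:
#   X123Y          missense (silent when X == Y)
#   X123*          stop gain
#   X123fs         frameshift
#   X123del[X]     single-residue in-frame deletion (optionally restating
#                  the deleted residue, e.g. T576delT)
#   X123_Y456del   in-frame deletion over a residue range
#   X123_Y456fs    frameshift anchored on a residue range
#   X123Y124fs     frameshift with a compound two-residue anchor
# Anything else (e.g. "ins" forms) parses as kind "other" with the raw
# string preserved.

#' Parse short protein-change notation
#'
#' @param raw Character vector of protein changes (e.g. `"R130G"`,
#'   `"W111*"`, `"L318fs"`, `"Y463_L466del"`).
#' @return `data.frame` with columns `raw`, `kind` (`missense`,
#'   `stop_gain`, `frameshift`, `inframe_del`, `silent`, `other`),
#'   `ref_aa`, `pos`, `end_aa`, `end_pos`, `new_aa` and `range_sep`
#'   (`"_"` for underscore ranges, `""` for compound anchors, `NA`
#'   otherwise).
#' @examples
#' parseProteinChange(c("W111*", "Y463_L466del", "T41T", "L318fs"))
#' @export
parseProteinChange <- function(raw) {
  if (length(raw) == 0)
    stop("parseProteinChange requires at least one string", call. = FALSE)
  if (any(is.na(raw) | !nzchar(raw)))
    stop("empty protein-change string", call. = FALSE)
  parse1 <- function(x) {
    out <- list(raw = x, kind = "other", ref_aa = NA_character_,
                pos = NA_integer_, end_aa = NA_character_,
                end_pos = NA_integer_, new_aa = NA_character_,
                range_sep = NA_character_)
    grab <- function(pat) {
      m <- regmatches(x, regexec(pat, x))[[1]]
      if (length(m)) m[-1] else NULL
    }
    if (!is.null(g <- grab("^([A-Z])([0-9]+)\\*$"))) {
      out[c("kind", "ref_aa", "pos")] <-
        list("stop_gain", g[1], as.integer(g[2]))
    } else if (!is.null(g <- grab("^([A-Z])([0-9]+)_([A-Z])([0-9]+)(fs|del)$"))) {
      out[c("kind", "ref_aa", "pos", "end_aa", "end_pos", "range_sep")] <-
        list(ifelse(g[5] == "fs", "frameshift", "inframe_del"),
             g[1], as.integer(g[2]), g[3], as.integer(g[4]), "_")
    } else if (!is.null(g <- grab("^([A-Z])([0-9]+)([A-Z])([0-9]+)fs$"))) {
      out[c("kind", "ref_aa", "pos", "end_aa", "end_pos", "range_sep")] <-
        list("frameshift", g[1], as.integer(g[2]), g[3], as.integer(g[4]),
             "")
    } else if (!is.null(g <- grab("^([A-Z])([0-9]+)fs$"))) {
      out[c("kind", "ref_aa", "pos")] <-
        list("frameshift", g[1], as.integer(g[2]))
    } else if (!is.null(g <- grab("^([A-Z])([0-9]+)del([A-Z]?)$"))) {
      out[c("kind", "ref_aa", "pos")] <-
        list("inframe_del", g[1], as.integer(g[2]))
      if (nzchar(g[3])) out$new_aa <- g[3]
    } else if (!is.null(g <- grab("^([A-Z])([0-9]+)([A-Z])$"))) {
      out[c("kind", "ref_aa", "pos", "new_aa")] <-
        list(ifelse(g[1] == g[3], "silent", "missense"),
             g[1], as.integer(g[2]), g[3])
    }
    if (!is.na(out$pos) && out$pos < 1)
      stop("protein position must be >= 1 in '", x, "'", call. = FALSE)
    if (!is.na(out$end_pos) && out$end_pos < out$pos)
      stop("range end precedes start in '", x, "'", call. = FALSE)
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(as.character(raw), parse1))
  rownames(out) <- NULL
  out
}

#' Re-serialize parsed protein changes
#'
#' Inverse of [parseProteinChange()] for grammar-conformant inputs; `other`
#' rows return their preserved raw string.
#'
#' @param parsed Output of [parseProteinChange()].
#' @return Character vector.
#' @export
formatProteinChange <- function(parsed) {
  vapply(seq_len(nrow(parsed)), function(i) {
    p <- parsed[i, ]
    switch(p$kind,
      other = p$raw,
      stop_gain = paste0(p$ref_aa, p$pos, "*"),
      silent = ,
      missense = paste0(p$ref_aa, p$pos, p$new_aa),
      frameshift = if (is.na(p$end_pos)) paste0(p$ref_aa, p$pos, "fs")
        else paste0(p$ref_aa, p$pos, p$range_sep, p$end_aa, p$end_pos, "fs"),
      inframe_del = if (!is.na(p$end_pos))
          paste0(p$ref_aa, p$pos, "_", p$end_aa, p$end_pos, "del")
        else paste0(p$ref_aa, p$pos, "del",
                    if (is.na(p$new_aa)) "" else p$new_aa))
  }, character(1))
}

#' Classify mutation consequences
#'
#' Maps parsed protein changes to the fine-grained consequence classes
#' used for reporting (`missense`, `stop`, `frameshift`, `inframe`,
#' `silent`, `other`), the coarser roll-up in which stop, frameshift and
#' in-frame changes aggregate into a `nonsense` bucket, and the
#' `truncating` indicator (stop or frameshift) consumed by driver
#' nomination. `other` rows are excluded from roll-up counts.
#'
#' @param x Character vector of raw protein changes, or the output of
#'   [parseProteinChange()].
#' @return `data.frame` with columns `raw`, `class`, `rollup`,
#'   `truncating`.
#' @examples
#' classifyConsequence(c("G12D", "W111*", "L318fs", "Y463_L466del", "T41T"))
#' @export
classifyConsequence <- function(x) {
  parsed <- if (is.data.frame(x)) x else parseProteinChange(x)
  cls <- c(missense = "missense", stop_gain = "stop",
           frameshift = "frameshift", inframe_del = "inframe",
           silent = "silent", other = "other")[parsed$kind]
  roll <- ifelse(cls %in% c("stop", "frameshift", "inframe"), "nonsense",
                 ifelse(cls == "other", "other", cls))
  data.frame(raw = parsed$raw, class = unname(cls), rollup = roll,
             truncating = cls %in% c("stop", "frameshift"),
             stringsAsFactors = FALSE)
}

#' Roll-up consequence counts
#'
#' Tabulates classified consequences into the missense / nonsense /
#' silent partition (excluding `other`).
#'
#' @param classified Output of [classifyConsequence()].
#' @return Named integer vector with entries `missense`, `nonsense`,
#'   `silent`.
#' @export
consequenceCounts <- function(classified) {
  keep <- classified$rollup != "other"
  tab <- table(factor(classified$rollup[keep],
                      levels = c("missense", "nonsense", "silent")))
  stats::setNames(as.integer(tab), names(tab))
}
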
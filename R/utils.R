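## Round half away from zero at a fixed number of decimals.  Reported
## percentages use commercial rounding (44.0945 -> 44.09, 36.995 -> 37.00)
## rather than the IEEE round-half-even of base round().
roundHalfUp <- function(x, digits = 0) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

## Colour aliases for size-ordered module labels, largest module first;
## "grey" is reserved for unassigned features.
MODULE_COLORS <- c(
    "turquoise", "blue", "brown", "yellow", "green", "red", "black",
    "pink", "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue")

moduleColorAlias <- function(i) {
    ifelse(i <= length(MODULE_COLORS), MODULE_COLORS[i],
           paste0("module", i))
}

## Derive a bounded per-stage seed from a run seed; offsets keep the
## result inside the 32-bit integer range R requires.
deriveSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) * 1000 + offset) %% 2147483647)
}

writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

readTsv <- function(path, ...) {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE, ...)
}
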
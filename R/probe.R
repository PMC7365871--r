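#' Build the fixed two-set probe montage
#'
#' Constructs the montage used throughout: two 3 x 5 optode probe sets (one
#' per hemisphere), each with eight emitters and seven detectors placed in a
#' checkerboard pattern, so that every grid-adjacent optode pair couples one
#' emitter with one detector. Each such pair is a measurement channel: 22
#' per set, 44 in total. Channels are numbered row by row within a set;
#' channels 1--22 belong to set 1 and 23--44 to set 2.
#'
#' @param separation nominal source-detector distance in cm (metadata only).
#' @return a \linkS4class{ProbeLayout}.
#' @examples
#' layout <- buildProbeLayout()
#' nChannels(layout)  # 44
#' @export
buildProbeLayout <- function(separation = 3) {
    rows <- 3L
    cols <- 5L
    nSets <- 2L

    ## checkerboard: emitter where (row + col) is even -> 8 emitters,
    ## 7 detectors on the 15 grid positions
    grid <- expand.grid(row = seq_len(rows), col = seq_len(cols))
    grid <- grid[order(grid$row, grid$col), ]
    grid$emitter <- (grid$row + grid$col) %% 2L == 0L
    grid$optode <- ave(seq_len(nrow(grid)), grid$emitter, FUN = seq_along)

    at <- function(r, c) grid[grid$row == r & grid$col == c, ]

    pairs <- list()
    for (r in seq_len(rows)) {
        for (c in seq_len(cols)) {
            here <- at(r, c)
            ## enumerate right and down neighbours once each
            for (d in list(c(0L, 1L), c(1L, 0L))) {
                r2 <- r + d[1]; c2 <- c + d[2]
                if (r2 > rows || c2 > cols) next
                there <- at(r2, c2)
                em <- if (here$emitter) here else there
                de <- if (here$emitter) there else here
                pairs[[length(pairs) + 1L]] <- data.frame(
                    emitter = em$optode, detector = de$optode,
                    erow = em$row, ecol = em$col,
                    drow = de$row, dcol = de$col)
            }
        }
    }
    pairs <- do.call(rbind, pairs)

    perSet <- nrow(pairs)
    channels <- do.call(rbind, lapply(seq_len(nSets), function(s) {
        cbind(
            data.frame(
                channel = (s - 1L) * perSet + seq_len(perSet),
                set = s,
                channelInSet = seq_len(perSet)),
            pairs)
    }))
    rownames(channels) <- NULL

    new("ProbeLayout",
        nSets = nSets, gridRows = rows, gridCols = cols,
        separation = separation, channels = channels)
}
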
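#' Packaged channel-anatomy lookup
#'
#' Static table of MNI coordinates and anatomical labels for the channels
#' reported as informative in the two native-language scenarios, shipped
#' with the package as plain CSV. Channels absent from the table have no
#' published localisation.
#'
#' @return data.frame with columns \code{channel}, \code{scenario},
#'   \code{hemisphere}, \code{mni_x}, \code{mni_y}, \code{mni_z},
#'   \code{anatomy}.
#' @export
channelAnatomyTable <- function() {
    path <- system.file("extdata", "channel_anatomy.csv",
                        package = "fnirsCCA", mustWork = TRUE)
    utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Annotate selected channels with anatomical information
#'
#' Joins a channel set against the packaged anatomy lookup
#' ([channelAnatomyTable()]). Channels without a published localisation
#' are labelled \code{"unlisted in paper"}.
#'
#' @param channels integer vector of channel indices in 1..44.
#' @return data.frame, one row per requested channel, ordered as given.
#' @examples
#' annotateChannels(c(1, 16))
#' @export
annotateChannels <- function(channels) {
    channels <- as.integer(channels)
    if (length(channels) == 0L)
        return(data.frame(channel = integer(), hemisphere = character(),
                          mni_x = numeric(), mni_y = numeric(),
                          mni_z = numeric(), anatomy = character()))
    if (any(channels < 1L | channels > 44L))
        stop("channel indices must lie in 1..44; got: ",
             paste(channels[channels < 1L | channels > 44L],
                   collapse = ", "))
    tab <- channelAnatomyTable()
    out <- data.frame(channel = channels)
    m <- match(channels, tab$channel)
    out$hemisphere <- ifelse(is.na(m), NA_character_, tab$hemisphere[m])
    out$mni_x <- tab$mni_x[m]
    out$mni_y <- tab$mni_y[m]
    out$mni_z <- tab$mni_z[m]
    out$anatomy <- ifelse(is.na(m), "unlisted in paper", tab$anatomy[m])
    out
}
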
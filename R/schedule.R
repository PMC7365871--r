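#' Generate a pseudo-randomised trial schedule
#'
#' Builds the block-design task schedule: two runs of 15 trials, five trials
#' per language (L1, L2, L3) per run, in a pseudo-random order with no two
#' consecutive trials in the same language. Each trial consists of an 18-s
#' question period, a reaction period of at most 3 s and a rest period of
#' 15--18 s. Onsets are the question onsets, measured from the start of the
#' recording; each run starts after a lead-in rest so that a 5-s pre-onset
#' baseline margin is always available.
#'
#' @param seed integer seed; the schedule is deterministic given the seed.
#' @param nRuns number of runs.
#' @param trialsPerLanguage trials per language per run.
#' @param questionDur question period duration in s.
#' @param reactionRange range the reaction period is drawn from (uniform), s.
#' @param restRange range the rest period is drawn from (uniform), s.
#' @param leadIn rest before the first trial of each run, s.
#' @param maxTries bounded number of attempts at an adjacency-free order.
#' @return data.frame with one row per trial: \code{run}, \code{trial},
#'   \code{onset} (s), \code{language}, \code{questionDur},
#'   \code{reactionDur}, \code{restDur}.
#' @examples
#' sched <- generateSchedule(seed = 1)
#' table(sched$language, sched$run)
#' @export
generateSchedule <- function(seed,
                             nRuns = 2L,
                             trialsPerLanguage = 5L,
                             questionDur = 18,
                             reactionRange = c(1, 3),
                             restRange = c(15, 18),
                             leadIn = 15,
                             maxTries = 1000L) {
    stopifnot(reactionRange[2] <= 3, restRange[1] >= 15, restRange[2] <= 18)
    withLocalSeed(seed, {
        langs <- c("L1", "L2", "L3")
        runs <- vector("list", nRuns)
        t0 <- 0
        for (r in seq_len(nRuns)) {
            order <- drawLanguageOrder(langs, trialsPerLanguage, maxTries)
            n <- length(order)
            reaction <- stats::runif(n, reactionRange[1], reactionRange[2])
            rest <- stats::runif(n, restRange[1], restRange[2])
            dur <- questionDur + reaction + rest
            onset <- t0 + leadIn + c(0, cumsum(dur[-n]))
            runs[[r]] <- data.frame(
                run = r, trial = seq_len(n), onset = onset,
                language = order, questionDur = questionDur,
                reactionDur = reaction, restDur = rest)
            t0 <- onset[n] + dur[n]
        }
        sched <- do.call(rbind, runs)
        rownames(sched) <- NULL
        validateSchedule(sched, trialsPerLanguage = trialsPerLanguage)
        sched
    })
}

## rejection-sample a language order with no same-language adjacency
drawLanguageOrder <- function(langs, perLanguage, maxTries) {
    pool <- rep(langs, each = perLanguage)
    for (i in seq_len(maxTries)) {
        cand <- sample(pool)
        if (!any(cand[-1] == cand[-length(cand)])) return(cand)
    }
    stop("could not satisfy the same-language adjacency constraint after ",
         maxTries, " attempts")
}

#' Validate a trial schedule
#'
#' Checks the schedule invariants: trial counts per run, balanced language
#' counts, no same-language adjacency, question duration 18 s, reaction
#' period at most 3 s and rest period within 15--18 s.
#'
#' @param schedule a schedule data.frame as built by [generateSchedule()].
#' @param trialsPerLanguage expected trials per language per run.
#' @return the schedule, invisibly; errors on violation.
#' @export
validateSchedule <- function(schedule, trialsPerLanguage = 5L) {
    need <- c("run", "trial", "onset", "language", "questionDur",
              "reactionDur", "restDur")
    if (!all(need %in% names(schedule)))
        stop("schedule is missing columns: ",
             paste(setdiff(need, names(schedule)), collapse = ", "))
    for (r in unique(schedule$run)) {
        s <- schedule[schedule$run == r, ]
        if (nrow(s) != 3L * trialsPerLanguage)
            stop("run ", r, " must contain ", 3L * trialsPerLanguage,
                 " trials")
        counts <- table(s$language)
        if (!all(counts == trialsPerLanguage))
            stop("run ", r, " must contain ", trialsPerLanguage,
                 " trials per language")
        if (any(s$language[-1] == s$language[-nrow(s)]))
            stop("run ", r, " has adjacent trials in the same language")
        if (any(diff(s$onset) <= 0))
            stop("run ", r, " onsets must be strictly increasing")
    }
    if (any(schedule$questionDur != 18))
        stop("question period must be 18 s")
    if (any(schedule$reactionDur < 0 | schedule$reactionDur > 3))
        stop("reaction period must lie in [0, 3] s")
    if (any(schedule$restDur < 15 | schedule$restDur > 18))
        stop("rest period must lie in [15, 18] s")
    invisible(schedule)
}

## evaluate expr with a local RNG state, restoring the caller's afterwards
withLocalSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(
            if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
                rm(".Random.seed", envir = globalenv()),
            add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}
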
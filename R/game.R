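#' Game configuration
#'
#' Numeric parameters of the headless obstacle-jumping game. Only the
#' structure is externally constrained (three difficulty levels with
#' increasing speed; level 1 spawns only small obstacles, level 3 only large
#' ones; coins appear from level 2); the concrete speeds, spawn cadence and
#' jump duration are package defaults, tunable here.
#'
#' @param speeds world speed (units/s) per level; must be strictly increasing.
#' @param p_large probability of a large obstacle per level; fixed endpoints
#'   `p_large[1] = 0` and `p_large[3] = 1`.
#' @param p_coin probability that a coin accompanies a spawn slot at levels
#'   with coins enabled.
#' @param spawn_interval_s mean time between obstacle spawns.
#' @param spawn_jitter_s half-width of the uniform jitter on the spawn
#'   interval (0 gives a strictly periodic, fully deterministic layout).
#' @param spawn_distance world distance from spawn point to the character.
#' @param jump_duration_s time the character stays airborne per jump.
#' @param obstacle_width_small,obstacle_width_large obstacle widths in world
#'   units; a jump must span the obstacle's whole passage time, so larger
#'   obstacles demand better-timed jumps.
#' @param window_s performance-evaluation cadence in seconds (default 15).
#' @param up_threshold,down_threshold success-rate thresholds for raising /
#'   lowering the difficulty; between them the level holds.
#' @param pause_s pause length after losing the last life.
#' @param dt_s simulation tick (s).
#' @return an object of class `game_config`.
#' @export
game_config <- function(speeds = c(1, 1.3, 1.6),
                        p_large = c(0, 0.5, 1),
                        p_coin = 0.3,
                        spawn_interval_s = 2,
                        spawn_jitter_s = 0.4,
                        spawn_distance = 3,
                        jump_duration_s = 0.7,
                        obstacle_width_small = 0.15,
                        obstacle_width_large = 0.45,
                        window_s = 15,
                        up_threshold = 0.8,
                        down_threshold = 0.4,
                        pause_s = 5,
                        dt_s = 0.02) {
  if (length(speeds) != 3L || is.unsorted(speeds, strictly = TRUE)) {
    stopf("speeds must be 3 strictly increasing values",
          class = "semgrip_config_error")
  }
  if (length(p_large) != 3L || p_large[1] != 0 || p_large[3] != 1) {
    stopf("p_large must be length 3 with p_large[1]=0 and p_large[3]=1",
          class = "semgrip_config_error")
  }
  if (down_threshold >= up_threshold) {
    stopf("down_threshold must be < up_threshold",
          class = "semgrip_config_error")
  }
  structure(as.list(environment()), class = "game_config")
}

#' Difficulty level parameters
#'
#' @param level difficulty level 1, 2 or 3.
#' @param config a [game_config()].
#' @return list with `level`, `game_speed`, `p_large_obstacle`,
#'   `coins_enabled`.
#' @export
difficulty_level <- function(level, config = game_config()) {
  level <- as.integer(level)
  if (!level %in% 1:3) stopf("level must be 1, 2 or 3")
  list(level = level,
       game_speed = config$speeds[level],
       p_large_obstacle = config$p_large[level],
       coins_enabled = level >= 2L)
}

#' Decide the next difficulty level from a performance window
#'
#' Success rate at or above the up-threshold raises the level (capped at 3);
#' at or below the down-threshold lowers it (floored at 1); in between, or
#' when no obstacle outcome resolved in the window, the level holds.
#'
#' @param successes,attempts cleared obstacles and total resolved obstacles
#'   in the window (coins are excluded from attempts).
#' @param current_level current level (1-3).
#' @param config a [game_config()] supplying the thresholds.
#' @return the new level.
#' @export
decide_difficulty <- function(successes, attempts, current_level,
                              config = game_config()) {
  if (attempts < 1) return(current_level)        # no decision without data
  rate <- successes / attempts
  if (rate >= config$up_threshold) {
    min(current_level + 1L, 3L)
  } else if (rate <= config$down_threshold) {
    max(current_level - 1L, 1L)
  } else {
    current_level
  }
}

#' Character colour for a life count
#'
#' @param lives remaining lives (1-3).
#' @return "green" (3), "yellow" (2) or "red" (1).
#' @export
life_color <- function(lives) {
  c("red", "yellow", "green")[as.integer(lives)]
}

#' Apply a collision to the game state
#'
#' Losing a life recolours the character (green, yellow, red for 3, 2, 1
#' lives). A collision on the last life pauses the game for five seconds,
#' resets the difficulty to level 1 and restores all three lives.
#'
#' @param state list with at least `lives`, `level`, `clock_s`,
#'   `paused_until_s`.
#' @param config a [game_config()].
#' @return the updated state.
#' @export
lose_life <- function(state, config = game_config()) {
  if (state$lives > 1L) {
    state$lives <- state$lives - 1L
  } else {
    state$paused_until_s <- state$clock_s + config$pause_s
    state$level <- 1L
    state$lives <- 3L
  }
  state$character_color <- life_color(state$lives)
  state
}

#' Run one headless game session
#'
#' Simulates the game on a fixed tick: obstacles (and, from level 2, coins)
#' spawn ahead of the character and arrive after `spawn_distance / speed`
#' seconds; a trigger makes the character jump for a fixed duration; an
#' obstacle is cleared only if the character is airborne for its entire
#' passage, otherwise it costs a life. Every `window_s` seconds of unpaused
#' play the success rate over the window decides the difficulty level. While
#' paused nothing spawns and no outcomes are logged.
#'
#' @param trigger_times sorted vector of trigger (squeeze/click) times in
#'   seconds from session start.
#' @param duration_s session length (default 300 s, one 5-minute game).
#' @param config a [game_config()].
#' @param seed integer seed; identical inputs and seed give identical logs.
#' @param start_level initial difficulty level.
#' @return an object of class `game_session_log`: a list with data frames
#'   `clicks` (`time_s`), `difficulty_changes` (`time_s`, `old_level`,
#'   `new_level`, `reason` — a performance decision or a lives reset) and
#'   `outcomes` (`time_s`, `kind` in `obstacle_cleared`,
#'   `coin_collected`, `collision`), plus `final_state`.
#' @export
run_game_session <- function(trigger_times, duration_s = 300,
                             config = game_config(), seed = 1L,
                             start_level = 1L) {
  if (is.unsorted(trigger_times)) stopf("trigger_times must be sorted")
  with_seed(seed, {
    st <- list(lives = 3L, level = as.integer(start_level),
               character_color = "green", clock_s = 0,
               paused_until_s = -Inf)
    clicks <- numeric(0)
    chg_t <- numeric(0); chg_old <- integer(0); chg_new <- integer(0)
    chg_reason <- character(0)
    out_t <- numeric(0); out_k <- character(0)
    airborne_until <- -Inf
    next_spawn <- config$spawn_interval_s
    next_eval <- config$window_s
    win_attempts <- 0L; win_successes <- 0L
    # pending arrivals: obstacles (arrive_s, width_s) and coins (arrive_s)
    obs_arrive <- numeric(0); obs_width <- numeric(0)
    coin_arrive <- numeric(0)
    trig <- trigger_times[trigger_times >= 0 & trigger_times <= duration_s]
    ti <- 1L
    dt <- config$dt_s
    n_ticks <- ceiling(duration_s / dt)
    for (k in seq_len(n_ticks)) {
      t0 <- (k - 1) * dt
      t1 <- min(k * dt, duration_s)
      st$clock_s <- t1
      paused <- t1 < st$paused_until_s
      # triggers landing in this tick
      while (ti <= length(trig) && trig[ti] < t1) {
        clicks <- c(clicks, trig[ti])
        if (!paused && trig[ti] >= airborne_until) {
          airborne_until <- trig[ti] + config$jump_duration_s
        }
        ti <- ti + 1L
      }
      if (paused) {
        # world frozen: push pending work past the pause
        next_spawn <- max(next_spawn, st$paused_until_s)
        next_eval <- max(next_eval, st$paused_until_s)
        if (length(obs_arrive)) {
          obs_arrive <- obs_arrive + dt
          coin_arrive <- coin_arrive + dt
        }
        next
      }
      # spawns
      while (next_spawn < t1) {
        lvl <- difficulty_level(st$level, config)
        lead <- config$spawn_distance / lvl$game_speed
        big <- runif(1) < lvl$p_large_obstacle
        w <- if (big) config$obstacle_width_large else config$obstacle_width_small
        obs_arrive <- c(obs_arrive, next_spawn + lead)
        obs_width <- c(obs_width, w / lvl$game_speed)
        if (lvl$coins_enabled && runif(1) < config$p_coin) {
          coin_arrive <- c(coin_arrive, next_spawn + lead +
                             config$spawn_interval_s / 2)
        }
        jit <- if (config$spawn_jitter_s > 0) {
          runif(1, -config$spawn_jitter_s, config$spawn_jitter_s)
        } else 0
        next_spawn <- next_spawn + config$spawn_interval_s + jit
      }
      # obstacle outcomes: resolved when the passage interval has fully elapsed
      done <- which(obs_arrive + obs_width <= t1)
      for (j in done) {
        if (obs_arrive[j] + obs_width[j] > duration_s) next
        cleared <- airborne_until >= obs_arrive[j] + obs_width[j] &&
          (airborne_until - config$jump_duration_s) <= obs_arrive[j]
        win_attempts <- win_attempts + 1L
        if (cleared) {
          win_successes <- win_successes + 1L
          out_t <- c(out_t, obs_arrive[j] + obs_width[j])
          out_k <- c(out_k, "obstacle_cleared")
        } else {
          out_t <- c(out_t, obs_arrive[j] + obs_width[j])
          out_k <- c(out_k, "collision")
          lvl_before <- st$level
          st <- lose_life(st, config)
          if (st$level != lvl_before) {       # last-life reset to level 1
            chg_t <- c(chg_t, obs_arrive[j] + obs_width[j])
            chg_old <- c(chg_old, lvl_before)
            chg_new <- c(chg_new, st$level)
            chg_reason <- c(chg_reason, "reset")
          }
          if (st$clock_s < st$paused_until_s) {
            # last life lost: drop everything in flight
            obs_arrive <- numeric(0); obs_width <- numeric(0)
            coin_arrive <- numeric(0)
            break
          }
        }
      }
      if (length(done) && length(obs_arrive)) {
        keep <- obs_arrive + obs_width > t1
        obs_arrive <- obs_arrive[keep]; obs_width <- obs_width[keep]
      }
      # coins: collected if airborne at arrival, silently missed otherwise
      cdone <- which(coin_arrive <= t1)
      for (j in cdone) {
        if (coin_arrive[j] > duration_s) next
        jump_start <- airborne_until - config$jump_duration_s
        if (airborne_until >= coin_arrive[j] && jump_start <= coin_arrive[j]) {
          out_t <- c(out_t, coin_arrive[j])
          out_k <- c(out_k, "coin_collected")
        }
      }
      if (length(cdone)) coin_arrive <- coin_arrive[coin_arrive > t1]
      # difficulty evaluation
      if (next_eval <= t1) {
        new_level <- decide_difficulty(win_successes, win_attempts,
                                       st$level, config)
        if (new_level != st$level) {
          chg_t <- c(chg_t, t1)
          chg_old <- c(chg_old, st$level)
          chg_new <- c(chg_new, as.integer(new_level))
          chg_reason <- c(chg_reason, "performance")
          st$level <- as.integer(new_level)
        }
        win_attempts <- 0L; win_successes <- 0L
        next_eval <- next_eval + config$window_s
      }
    }
    ord <- order(out_t)
    structure(
      list(clicks = data.frame(time_s = clicks),
           difficulty_changes = data.frame(time_s = chg_t,
                                           old_level = chg_old,
                                           new_level = chg_new,
                                           reason = chg_reason,
                                           stringsAsFactors = FALSE),
           outcomes = data.frame(time_s = out_t[ord],
                                 kind = out_k[ord],
                                 stringsAsFactors = FALSE),
           final_state = st,
           duration_s = duration_s),
      class = "game_session_log"
    )
  })
}

#' @export
print.game_session_log <- function(x, ...) {
  kinds <- table(factor(x$outcomes$kind,
                        c("obstacle_cleared", "coin_collected", "collision")))
  cat(sprintf(paste0("<game_session_log> %.0f s: %d clicks, %d cleared, ",
                     "%d coins, %d collisions, %d level changes\n"),
              x$duration_s, nrow(x$clicks), kinds[1], kinds[2], kinds[3],
              nrow(x$difficulty_changes)))
  invisible(x)
}
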
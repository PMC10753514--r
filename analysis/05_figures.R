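#!/usr/bin/env Rscript
# Stage 5 — figures (written under scratch/, not part of the result tables):
# RMR and matched body temperature by method and ambient temperature, and
# the per-bird variability indices by method.

suppressMessages({
  library(tbmethods)
  library(ggplot2)
})

est <- read.csv("results/metabolic_estimates.csv")
vari <- read.csv("results/variability.csv")
est$t_air <- factor(est$t_air, levels = c(-15, 5, 25))
dir.create("scratch/figures", showWarnings = FALSE, recursive = TRUE)

p1 <- ggplot(est, aes(t_air, rmr_w, colour = method)) +
  geom_jitter(width = 0.15, alpha = 0.4, size = 1) +
  stat_summary(fun = mean, fun.min = function(x) mean(x) - sd(x),
               fun.max = function(x) mean(x) + sd(x), geom = "pointrange",
               position = position_dodge(width = 0.5), size = 0.3) +
  labs(x = "Ambient temperature (degC)", y = "RMR (W)",
       colour = "Method") +
  theme_classic()
ggsave("scratch/figures/rmr_by_method.pdf", p1, width = 6, height = 4)

p2 <- ggplot(subset(est, method != "C"),
             aes(t_air, tb_mean, colour = method)) +
  geom_jitter(width = 0.15, alpha = 0.4, size = 1) +
  stat_summary(fun = mean, fun.min = function(x) mean(x) - sd(x),
               fun.max = function(x) mean(x) + sd(x), geom = "pointrange",
               position = position_dodge(width = 0.5), size = 0.3) +
  labs(x = "Ambient temperature (degC)", y = "Body temperature (degC)",
       colour = "Method") +
  theme_classic()
ggsave("scratch/figures/tb_by_method.pdf", p2, width = 6, height = 4)

long <- rbind(data.frame(method = vari$method, index = "CV (%)",
                         value = vari$cv),
              data.frame(method = vari$method, index = "D",
                         value = vari$d_index))
p3 <- ggplot(long, aes(method, value)) +
  geom_jitter(width = 0.1, alpha = 0.5) +
  stat_summary(fun = mean, fun.min = function(x) mean(x) - sd(x),
               fun.max = function(x) mean(x) + sd(x), geom = "pointrange",
               colour = "firebrick", size = 0.3) +
  facet_wrap(~index, scales = "free_y") +
  labs(x = "Method", y = "Variability of the night profile") +
  theme_classic()
ggsave("scratch/figures/variability_by_method.pdf", p3, width = 7, height = 4)

cat("wrote figures under scratch/figures/\n")
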
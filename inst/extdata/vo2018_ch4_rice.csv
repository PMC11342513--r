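# Methane emission from rice production at three field sites near Hue,
# central Vietnam, early-year cropping season 2018 (closed static-chamber
# flux measurements; source: Vo et al. 2018, Vietnamese rice CH4 study).
# n = 10 sampling dates per season at every site; daily emission in
# kg CH4 ha-1 day-1, yield in ton ha-1.
site,daily_mean,daily_sd,period_days,yield_t_ha,n
C2,1.444,0.058,109,7.6,10
C3,1.948,0.019,110,7.5,10
C4,1.853,0.088,108,7.3,10
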
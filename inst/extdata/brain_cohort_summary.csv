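scanner,tissue,analysis,n_patients,n_scans,mean_adc,sd_adc,rc_printed,wcv_printed
ge_signa_architect,white_matter,repeatability,0,0,NA,NA,NA,NA
philips_ingenia,white_matter,repeatability,3,6,807.7,16.7,46.3,2.1
siemens_avanto,white_matter,repeatability,14,28,801.4,16.2,44.9,2.0
ge_signa_architect,csf,repeatability,0,0,NA,NA,NA,NA
philips_ingenia,csf,repeatability,3,6,3079.4,63.6,176.3,2.1
siemens_avanto,csf,repeatability,14,28,3013.0,59.9,166.1,2.0
ge_signa_architect,white_matter,reproducibility,3,3,843.7,15.3,42.5,1.8
philips_ingenia,white_matter,reproducibility,14,17,813.7,15.4,42.7,1.9
siemens_avanto,white_matter,reproducibility,17,35,803.7,15.2,42.1,1.9
ge_signa_architect,csf,reproducibility,3,3,3156.5,65.9,182.6,2.1
philips_ingenia,csf,reproducibility,14,17,3114.7,63.5,175.9,2.0
siemens_avanto,csf,reproducibility,17,35,3011.0,60.4,167.2,2.0
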
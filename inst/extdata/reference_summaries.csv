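panel,variable,plexus,region,control_mean,control_sd,case_mean,case_sd,printed_difference,printed_p
functional,va_logmar,NA,NA,0.03,0.05,0.24,0.28,-0.27,0.020
functional,mferg_ring1_uv,NA,NA,139.35,28.27,81.82,36.71,57.43,0.001
functional,mferg_ring2_uv,NA,NA,63.21,14.19,21.78,9.79,41.43,0.001
functional,mferg_ring3_uv,NA,NA,33.80,7.36,7.98,3.95,25.82,0.001
functional,mferg_ring4_uv,NA,NA,22.58,4.78,6.55,5.11,16.02,0.001
functional,mferg_ring5_uv,NA,NA,16.24,4.06,4.15,3.02,12.09,0.001
functional,da001_amplitude_uv,NA,NA,203.35,22.68,38.94,31.25,164.41,0.001
functional,da001_latency_ms,NA,NA,95.70,10.92,88.73,24.07,6.98,0.116
functional,da30_amplitude_uv,NA,NA,210.58,19.62,31.96,29.05,178.62,0.001
functional,da30_latency_ms,NA,NA,44.12,6.77,60.11,24.39,-15.99,0.001
functional,la30_amplitude_uv,NA,NA,124.28,16.96,13.26,10.56,111.02,0.001
functional,la30_latency_ms,NA,NA,27.54,2.75,38.23,6.15,-10.69,0.001
functional,flicker_amplitude_uv,NA,NA,69.58,10.52,10.22,10.18,59.35,0.001
functional,flicker_latency_ms,NA,NA,27.97,2.54,34.48,5.81,-6.5,0.001
perfusion_density,pd,SCP,medium_central,34.15,5.19,34.94,6.12,-0.8,0.600
perfusion_density,pd,SCP,large_central,42.09,5.77,37.12,5.41,4.97,0.001
perfusion_density,pd,SCP,superior,46.82,11.41,34.55,11.18,12.26,0.001
perfusion_density,pd,SCP,temporal,26.75,7.75,21.73,8.04,5.02,0.016
perfusion_density,pd,SCP,inferior,49.46,9.52,36.96,9.38,12.51,0.001
perfusion_density,pd,SCP,tight_central,19.81,9.45,23.34,9.31,-5.53,0.121
perfusion_density,pd,DCP,medium_central,40.32,8.36,28.30,7.68,12.02,0.001
perfusion_density,pd,DCP,large_central,45.64,7.66,30.09,7.25,15.55,0.001
perfusion_density,pd,DCP,superior,43.13,11.33,31.55,8.67,11.58,0.001
perfusion_density,pd,DCP,temporal,35.13,7.30,19.63,7.49,15.5,0.001
perfusion_density,pd,DCP,inferior,48.59,8.44,33.01,6.93,15.58,0.001
perfusion_density,pd,DCP,tight_central,17.16,6.33,17.44,6.54,-0.28,0.870
perfusion_density,pd,CC,medium_central,84.29,1.86,78.85,3.71,5.43,0.001
perfusion_density,pd,CC,large_central,84.29,1.80,79.39,3.09,4.9,0.001
perfusion_density,pd,CC,superior,83.73,2.26,78.51,3.14,5.22,0.001
perfusion_density,pd,CC,temporal,85.84,1.54,77.89,4.90,7.95,0.001
perfusion_density,pd,CC,inferior,83.99,1.81,76.41,6.55,7.57,0.001
perfusion_density,pd,CC,tight_central,83.93,1.78,77.83,4.32,6.09,0.001
vessel_length_density,vld,SCP,medium_central,19.50,1.43,19.17,1.78,0.33,0.423
vessel_length_density,vld,SCP,large_central,19.16,1.01,17.62,1.53,1.54,0.001
vessel_length_density,vld,SCP,superior,19.83,2.22,16.79,0.98,3.04,0.001
vessel_length_density,vld,SCP,temporal,20.52,2.00,19.50,2.61,1.03,0.106
vessel_length_density,vld,SCP,inferior,19.66,1.44,16.53,0.72,3.13,0.001
vessel_length_density,vld,SCP,tight_central,20.04,1.53,19.52,2.39,0.52,0.351
vessel_length_density,vld,DCP,medium_central,22.25,2.22,20.80,1.02,1.46,0.001
vessel_length_density,vld,DCP,large_central,22.49,2.10,20.88,1.80,1.60,0.016
vessel_length_density,vld,DCP,superior,22.48,2.35,20.15,1.44,2.33,0.001
vessel_length_density,vld,DCP,temporal,22.93,4.00,20.58,2.38,2.35,0.005
vessel_length_density,vld,DCP,inferior,22.35,4.01,19.63,1.46,2.72,0.008
vessel_length_density,vld,DCP,tight_central,17.37,2.92,19.57,1.46,2.2,0.001
vessel_length_density,vld,CC,medium_central,10.85,0.98,8.66,1.04,2.19,0.001
vessel_length_density,vld,CC,large_central,10.67,0.78,8.71,1.03,1.95,0.001
vessel_length_density,vld,CC,superior,10.35,0.98,8.91,1.35,1.44,0.001
vessel_length_density,vld,CC,temporal,10.84,1.35,8.30,1.15,2.54,0.001
vessel_length_density,vld,CC,inferior,11.05,1.03,8.89,1.28,2.16,0.001
vessel_length_density,vld,CC,tight_central,11.10,1.23,8.74,1.09,2.36,0.001
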
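station_id,mean_official,mean_raw,mean_lso,pearson_raw,pearson_lso,mae_raw,mae_lso,rmse_raw,rmse_lso
Kardinaal de Jong,10.3,8.0,8.9,0.86,0.82,3.8,3.4,4.3,4.5
Griftpark,9.3,8.3,9.1,0.84,0.81,3.5,3.2,4.7,4.6
Breukelen,9.0,7.9,9.1,0.82,0.83,3.6,2.9,4.9,4.2
Cabauw,8.8,8.4,10.0,0.73,0.75,4.1,3.6,6.0,5.4
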
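id,scl_cm,mass_kg,release_date,acoustic_duration_d,satellite_duration_d,acoustic_raw_detections,satellite_raw_locations,acoustic_locations_per_day
A,56.2,24.8,2017-05-02,80,74,3529,344,10
B,40.2,9.4,2017-05-03,NA,234,NA,1651,NA
C,49.6,16.1,2017-05-02,237,53,6365,906,1
D,38.9,5.6,2017-05-03,102,100,3723,649,6
E,37.6,5.7,2017-05-03,42,130,231,1000,1
F,41.9,6.5,2017-05-02,81,NA,2854,NA,9
G,38.7,7.5,2017-05-02,68,152,3139,1178,14
H,51.0,14.5,2017-05-03,8,20,46,129,2
I,52.4,18.8,2017-05-03,81,186,385,1253,1
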
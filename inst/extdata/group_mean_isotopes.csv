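specimen_id,group,n_specimens,d15n_glu,d15n_phe
fresh_mean,fresh,3,17.4,7.3
starved_mean,starved,3,20.0,14.4
alga_mean,alga,1,12.3,8.8
adductor_mean,adductor_muscle,3,16.1,5.5
zoox_mean,zooxanthellae,3,8.2,5.3
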
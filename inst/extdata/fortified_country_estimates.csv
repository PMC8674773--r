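country,vehicle,region_group,mean_natural_total,sd_natural_total,mean_natural_less_ohd,sd_natural_less_ohd,mean_fortified_total,sd_fortified_total,mean_fortified_less_ohd,sd_fortified_less_ohd
Finland,milk,europe_north_america,7.9,0.2,7.2,0.2,10.8,0.2,10.4,0.2
United States of America,milk,europe_north_america,5.1,0.0,4.5,0.0,7.2,1.1,6.7,1.1
Canada,milk,europe_north_america,4.8,0.1,4.3,0.0,6.2,0.1,5.9,0.1
Sweden,milk,europe_north_america,6.0,0.1,5.3,0.1,6.3,0.3,5.8,0.3
Jordan,wheat_flour,middle_east,1.6,0.1,1.5,0.1,5.9,0.2,5.8,0.2
Kuwait,wheat_flour,middle_east,3.4,0.1,3.0,0.1,6.2,1.9,6.0,1.9
United Arab Emirates,wheat_flour,middle_east,3.9,0.2,3.5,0.1,6.7,1.9,6.5,1.9
Saudi Arabia,wheat_flour,middle_east,2.8,0.0,2.6,0.0,5.5,1.8,5.4,1.8
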
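# published national and regional averages (with national max/min) of the oldest-old QoL index, waves 2005/2010/2015
year,national,maximum,maximum_province,minimum,minimum_province,east,central,west,northeast
2005,0.5595,0.8662,Shanghai,0.1521,Tibet,0.6395,0.6705,0.5414,0.5637
2010,0.5704,0.8147,Beijing,0.1163,Tibet,0.6626,0.6552,0.5226,0.6450
2015,0.5833,0.7943,Beijing,0.0804,Tibet,0.6715,0.6649,0.5220,0.6456
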
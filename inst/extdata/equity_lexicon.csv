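category,pattern
people_of_color,people of color
people_of_color,community of color
people_of_color,communities of color
people_of_color,colored
people_of_color,poc
people_of_color,woc
people_of_color,woman of color
people_of_color,minority
people_of_color,minorities
people_of_color,racial disparity
people_of_color,racial disparities
people_of_color,racism
black,black*
black,african american*
black,af american
black,brown
black,blk
black,blm
black,brother
black,brotha
black,m4bl
black,sister
black,sista
hispanic_latino,hispanic*
hispanic_latino,latino*
hispanic_latino,latinx*
hispanic_latino,latina*
indigenous,indigenous
indigenous,american indian*
indigenous,native american*
asian,asian*
asian,asian american*
crc_topic,coloncancer
crc_topic,colorectalcancer
crc_topic,colon cancer
crc_topic,colorectal cancer
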
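# Approximate first-order contiguity of the 47 Kenyan counties.
# Hand-curated from the administrative map (queen-like contiguity);
# NOT derived from official shapefiles. One undirected edge per line.
Mombasa Kwale
Mombasa Kilifi
Kwale Kilifi
Kwale Taita-Taveta
Kilifi Tana-River
Kilifi Taita-Taveta
Tana-River Lamu
Tana-River Garissa
Tana-River Isiolo
Tana-River Kitui
Lamu Garissa
Taita-Taveta Makueni
Taita-Taveta Kajiado
Taita-Taveta Kitui
Garissa Wajir
Garissa Isiolo
Wajir Mandera
Wajir Marsabit
Wajir Isiolo
Marsabit Turkana
Marsabit Samburu
Marsabit Isiolo
Isiolo Meru
Isiolo Laikipia
Isiolo Samburu
Meru Tharaka-Nithi
Meru Nyeri
Meru Laikipia
Tharaka-Nithi Embu
Tharaka-Nithi Kitui
Embu Kitui
Embu Machakos
Embu Kirinyaga
Kitui Machakos
Kitui Makueni
Machakos Makueni
Machakos Kajiado
Machakos Nairobi
Machakos Kiambu
Machakos Muranga
Makueni Kajiado
Nairobi Kiambu
Nairobi Kajiado
Kiambu Muranga
Kiambu Nyandarua
Kiambu Nakuru
Kiambu Kajiado
Muranga Kirinyaga
Muranga Nyeri
Muranga Nyandarua
Kirinyaga Nyeri
Nyeri Nyandarua
Nyeri Laikipia
Nyandarua Nakuru
Nyandarua Laikipia
Laikipia Samburu
Laikipia Baringo
Laikipia Nakuru
Samburu Turkana
Samburu Baringo
Turkana West-Pokot
Turkana Baringo
West-Pokot Baringo
West-Pokot Elgeyo-Marakwet
West-Pokot Trans-Nzoia
Trans-Nzoia Elgeyo-Marakwet
Trans-Nzoia Uasin-Gishu
Trans-Nzoia Bungoma
Elgeyo-Marakwet Baringo
Elgeyo-Marakwet Uasin-Gishu
Uasin-Gishu Baringo
Uasin-Gishu Nandi
Uasin-Gishu Kericho
Uasin-Gishu Kakamega
Nandi Kakamega
Nandi Vihiga
Nandi Kisumu
Nandi Kericho
Baringo Nakuru
Baringo Kericho
Nakuru Narok
Nakuru Bomet
Nakuru Kericho
Narok Bomet
Narok Kajiado
Narok Kisii
Narok Migori
Narok Nyamira
Kericho Bomet
Kericho Kisumu
Kericho Nyamira
Bomet Nyamira
Kakamega Bungoma
Kakamega Busia
Kakamega Siaya
Kakamega Vihiga
Vihiga Kisumu
Vihiga Siaya
Bungoma Busia
Busia Siaya
Siaya Kisumu
Kisumu Nyamira
Kisumu Homa-Bay
Homa-Bay Kisii
Homa-Bay Migori
Migori Kisii
Kisii Nyamira
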
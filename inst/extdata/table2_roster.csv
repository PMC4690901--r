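network,category,name,multiplicity
UHSN,wholesale_club,B. Green Wholesale East,1
UHSN,wholesale_club,B. Green Wholesale West,1
UHSN,wholesale_club,BJ's Wholesale Club,1
UHSN,wholesale_club,Costco Wholesale,1
UHSN,wholesale_club,Eastern Food Services,1
UHSN,wholesale_club,George J. Falter Co.,1
UHSN,wholesale_club,Jetro Cash & Carry,1
UHSN,wholesale_club,LG Wholesale,1
UHSN,wholesale_club,Maryland Cash & Carry,1
UHSN,wholesale_club,Restaurant Depot,1
UHSN,wholesale_club,Sam's Club,1
UHSN,snacks,Berliner Specialty Distributors (ice cream),1
UHSN,snacks,Blue Bunny (ice cream),1
UHSN,snacks,Brigg's Ice Cream Co.,1
UHSN,snacks,Frito Lay,1
UHSN,snacks,Herr's Snacks,1
UHSN,snacks,McKee Foods,1
UHSN,snacks,Raylicious,1
UHSN,snacks,Stone Creek Countrywide Snacks,1
UHSN,snacks,Tastykake,1
UHSN,snacks,Utz Quality Foods,1
UHSN,specialty_foods,Farmer's market,1
UHSN,specialty_foods,Hauswald Bakery,1
UHSN,specialty_foods,Sponseller's Egg Co.,1
UHSN,specialty_foods,Zeke's Coffee,1
UHSN,beverages,Arizona Beverages USA,1
UHSN,beverages,Canada Dry,1
UHSN,beverages,Coca-Cola Company,1
UHSN,beverages,Everfresh Beverages,1
UHSN,beverages,PepsiCo,1
UHSN,supermarket_grocery,Food Depot,1
UHSN,supermarket_grocery,Giant Food Stores,1
UHSN,supermarket_grocery,Mars Supermarkets,1
UHSN,supermarket_grocery,Martin's Food Markets,1
UHSN,supermarket_grocery,Safeway,1
UHSN,supermarket_grocery,Save-A-Lot,1
UHSN,supermarket_grocery,Shoppers Foods and Pharmacy,1
UHSN,supermarket_grocery,Stop Shop and Save,1
UHSN,discount_department,Dollar Mark,1
UHSN,discount_department,Walmart,1
UHSN,meat_market,Manger Packing Corporation,1
HSN,wholesale_club,B. Green Wholesale East,1
HSN,wholesale_club,B. Green Wholesale West,1
HSN,wholesale_club,BJ's Wholesale Club,1
HSN,wholesale_club,Costco Wholesale,1
HSN,wholesale_club,Jetro Cash & Carry,1
HSN,wholesale_club,Maryland Cash & Carry,2
HSN,wholesale_club,Sam's Club,1
HSN,snacks,McKee Foods,1
HSN,snacks,Utz Quality Foods,1
HSN,supermarket_grocery,Giant Food Stores,1
HSN,supermarket_grocery,Wegmans,1
HSN,supermarket_grocery,Safeway,1
HSN,supermarket_grocery,Save-A-Lot,1
HSN,discount_department,Walmart,1
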
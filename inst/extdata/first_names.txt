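Aaron
Abigail
Adam
Aiden
Alice
Amber
Amelia
Amy
Andrew
Anna
Ashley
Austin
Bella
Benjamin
Blake
Brandon
Brian
Caleb
Cameron
Carla
Carter
Chloe
Chris
Claire
Connor
Daniel
David
Dylan
Elena
Eli
Ella
Emily
Emma
Ethan
Evan
Fiona
Gavin
Grace
Hannah
Henry
Isaac
Isabella
Jack
Jacob
James
Jasmine
Jason
Jenna
Jeremy
Jessica
John
Jordan
Joseph
Julia
Kayla
Kevin
Kyle
Laura
Lauren
Liam
Lily
Logan
Lucas
Luke
Maria
Mason
Matthew
Megan
Mia
Michael
Molly
Natalie
Nathan
Nicole
Noah
Olivia
Owen
Paige
Peter
Rachel
Rebecca
Ryan
Samuel
Sarah
Sophia
Steven
Sydney
Thomas
Tyler
Victoria
William
Zachary
Zoe
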